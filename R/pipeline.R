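#' Run the full richness-analysis pipeline from a configuration
#'
#' Executes the requested stages in order — simulate (synthetic world) ->
#' richness -> hotspot -> nestedness -> cooccur -> envmodel -> biogeo —
#' writing per-stage CSV/JSON results, a log with seeds and runtimes, and a
#' machine-readable manifest with a content hash per output. Every
#' stochastic stage must carry an explicit `seed`; unknown configuration
#' keys are rejected before any computation.
#'
#' @param config a named list, or the path to a YAML file holding one. Top
#'   level keys: `stages` (character vector), `out_dir`, and one block per
#'   stage. See the packaged demo config
#'   (`system.file("extdata", "demo-config.yaml", package = "macrorich")`).
#' @return Invisibly, the run directory path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logf <- file.path(out, "run.log")
  manifest <- list()
  log_line <- function(...) cat(..., "\n", sep = "", file = logf,
                                append = TRUE)
  cat("macrorich ", as.character(utils::packageVersion("macrorich")),
      " pipeline run, R ", R.version.string, "\n", sep = "", file = logf)

  emit <- function(name, writer) {
    path <- file.path(out, name)
    writer(path)
    manifest[[name]] <<- unname(tools::md5sum(path))
    path
  }
  state <- new.env(parent = emptyenv())

  for (stage in cfg$stages) {
    t0 <- proc.time()[3]
    p <- cfg[[stage]]
    switch(stage,
      simulate = {
        state$env <- make_environment(shape = p$shape, decay = p$decay,
                                      noise_sd = p$noise_sd, seed = p$seed)
        state$ranges <- make_ranges(p$n_species, state$env, seed = p$seed)
        emit("environment_PET.asc", function(f)
          write_grid(state$env$layers$PET, f,
                     cell_size = state$env$cell_size))
      },
      richness = {
        state$grid <- stack_richness(state$ranges)
        state$pam <- build_matrix(state$ranges)
        emit("richness.asc", function(f) write_grid(state$grid, f))
        emit("presence_absence.csv", function(f) write_matrix(state$pam, f))
      },
      hotspot = {
        Wg <- build_weights(state$grid, scheme = p$weights,
                            include_self = TRUE)
        Wm <- build_weights(state$grid, scheme = p$weights)
        vals <- state$grid$richness[state$grid$valid]
        mi <- morans_i(vals, Wm)
        z <- getis_ord_gstar(vals, Wg)
        hs <- delineate_hotspots(z, Wg, alpha = p$alpha,
                                 correction = p$correction)
        emit("hotspot_cells.csv", function(f)
          utils::write.csv(data.frame(row = hs$cells[, 1],
                                      col = hs$cells[, 2], z = hs$z,
                                      p = hs$p, p_adj = hs$p_adj,
                                      cluster = hs$cluster), f,
                           row.names = FALSE))
        emit("hotspot_clusters.csv", function(f)
          utils::write.csv(hs$clusters, f, row.names = FALSE))
        emit("morans_i.json", function(f)
          jsonlite::write_json(mi[c("I", "expected", "z", "p")], f,
                               auto_unbox = TRUE, digits = NA))
        state$hotspots <- hs
      },
      nestedness = {
        res <- lapply(p$indices, function(ix)
          nestedness_test(state$pam, ix, n_iter = p$iters, seed = p$seed))
        emit("nestedness.csv", function(f)
          utils::write.csv(do.call(rbind, lapply(res, function(r)
            data.frame(index = r$index, observed = r$observed,
                       null_mean = r$null_mean, ci_low = r$ci[1],
                       ci_high = r$ci[2], p = r$p, tail = r$tail))), f,
            row.names = FALSE))
      },
      cooccur = {
        cs <- cooccurrence_test(state$pam, n_null = p$nulls, seed = p$seed)
        emit("cooccurrence.csv", function(f)
          utils::write.csv(data.frame(c_score = cs$observed,
                                      null_mean = cs$null_mean,
                                      null_variance = cs$null_variance,
                                      ses = cs$ses, p_less = cs$p_less,
                                      p_greater = cs$p_greater,
                                      n_null = cs$n_null), f,
                           row.names = FALSE))
      },
      envmodel = {
        st <- site_table(state$grid, state$env)
        cand <- setdiff(names(st), c("longitude", "latitude", "richness"))
        ols <- forward_stepwise(st, "richness", cand)
        Wr <- build_weights(state$grid, row_standardize = TRUE)
        sar <- sar_fit(st, ols$selected, Wr)
        qe <- quantile_envelope(st[[p$energy]], st$richness,
                                taus = p$quantiles, n_boot = p$boot,
                                seed = p$seed)
        emit("env_models.csv", function(f) {
          both <- merge(ols$coefficients, sar$coefficients, by = "term",
                        suffixes = c("_ols", "_sar"), sort = FALSE)
          utils::write.csv(both, f, row.names = FALSE)
        })
        emit("env_envelope.csv", function(f)
          utils::write.csv(qe$fits, f, row.names = FALSE))
      },
      biogeo = {
        tree <- read_tree(p$tree)
        coding <- read_coding(p$coding, tree = tree)
        fits <- list(fit_dec(tree, coding, "DEC"),
                     fit_dec(tree, coding, "DEC+j"))
        cmp <- compare_models(fits)
        best <- fits[[which.min(vapply(fits, `[[`, 0, "aic"))]]
        bs <- bsm(tree, coding, best, n_maps = p$maps, seed = p$seed)
        emit("biogeo_models.csv", function(f)
          utils::write.csv(cmp, f, row.names = FALSE))
        emit("biogeo_dispersal.csv", function(f)
          utils::write.csv(as.data.frame(bs$dispersal), f))
      }
    )
    log_line(sprintf("stage %-10s %6.2fs seed=%s", stage,
                     proc.time()[3] - t0,
                     if (is.null(p$seed)) "-" else p$seed))
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out)
}

## Stage vocabulary, per-stage defaults, and which stages are stochastic
## (and therefore must carry an explicit seed).
pipeline_schema <- function() {
  list(
    simulate = list(defaults = list(shape = c(20, 20), decay = 5,
                                    noise_sd = 0.05, n_species = 50),
                    stochastic = TRUE),
    richness = list(defaults = list(), stochastic = FALSE),
    hotspot = list(defaults = list(weights = "queen", alpha = 0.05,
                                   correction = "fdr"),
                   stochastic = FALSE),
    nestedness = list(defaults = list(indices = c("T", "BR", "NODF"),
                                      iters = 10000),
                      stochastic = TRUE),
    cooccur = list(defaults = list(nulls = 50000), stochastic = TRUE),
    envmodel = list(defaults = list(energy = "PET",
                                    quantiles = c(0.01, 0.99),
                                    boot = 10000),
                    stochastic = TRUE),
    biogeo = list(defaults = list(maps = 1000), stochastic = TRUE)
  )
}

validate_config <- function(config) {
  schema <- pipeline_schema()
  known_top <- c("stages", "out_dir", names(schema))
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$stages) || !length(config$stages))
    stop("config must list at least one stage", call. = FALSE)
  bad <- setdiff(config$stages, names(schema))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(config$out_dir)) stop("config needs 'out_dir'", call. = FALSE)
  for (stage in config$stages) {
    block <- config[[stage]]
    if (is.null(block)) block <- list()
    unknown <- setdiff(names(block),
                       c(names(schema[[stage]]$defaults), "seed",
                         "tree", "coding"))
    if (length(unknown))
      stop("unknown key(s) in stage '", stage, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (schema[[stage]]$stochastic && is.null(block$seed))
      stop("stochastic stage '", stage, "' needs an explicit seed",
           call. = FALSE)
    for (k in names(schema[[stage]]$defaults))
      if (is.null(block[[k]])) block[[k]] <- schema[[stage]]$defaults[[k]]
    if (stage == "simulate" && length(block$shape) == 2)
      block$shape <- unlist(block$shape)
    if (stage == "envmodel") block$quantiles <- unlist(block$quantiles)
    config[[stage]] <- block
  }
  if ("biogeo" %in% config$stages &&
      (is.null(config$biogeo$tree) || is.null(config$biogeo$coding)))
    stop("stage 'biogeo' needs 'tree' and 'coding' input paths",
         call. = FALSE)
  config
}
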