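#' Construct a tip range coding over a set of areas
#'
#' @param tips character vector of tip labels.
#' @param ranges character vector of range strings (e.g. `"B"`, `"BC"`),
#'   one per tip, each a non-empty subset of `areas`.
#' @param areas ordered character vector of single-letter area names; the
#'   bitmask encoding of ranges is fixed by this order.
#' @return An object of class `range_coding`: `areas`, `ranges` (named by
#'   tip).
#' @export
range_coding <- function(tips, ranges, areas) {
  stopifnot(length(tips) == length(ranges))
  if (any(nchar(areas) != 1)) stop("areas must be single characters",
                                   call. = FALSE)
  for (rng in ranges) {
    m <- areas_to_mask(rng, areas)   # errors on unknown areas
    if (m == 0L) stop("tip ranges must be non-empty", call. = FALSE)
  }
  structure(list(areas = areas, ranges = stats::setNames(ranges, tips)),
            class = "range_coding")
}

## Parameter-independent setup: validation, state space, tip states,
## postorder tree. Computed once per (tree, coding) and reused across
## likelihood evaluations during optimization.
dec_static <- function(tree, coding, max_range_size,
                       dispersal_matrix = NULL) {
  check_tree(tree)
  stopifnot(inherits(coding, "range_coding"))
  missing_tips <- setdiff(tree$tip.label, names(coding$ranges))
  if (length(missing_tips))
    stop("coding missing tips: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  areas <- coding$areas
  states <- dec_states(length(areas), max_range_size)
  tip_state <- vapply(tree$tip.label, function(tp)
    state_of(areas_to_mask(coding$ranges[[tp]], areas), states), 0L)
  list(tree = stats::reorder(tree, "postorder"), areas = areas,
       states = states, tip_state = tip_state,
       dispersal_matrix = dispersal_matrix,
       cache = new.env(parent = emptyenv()))
}

## Per-state cladogenesis tables (state indices + probabilities) for a jump
## weight j, restricted to states allowed under the maximum range size.
dec_clado_tables <- function(states, nA, j) {
  clado <- vector("list", length(states$masks))
  for (si in seq_along(states$masks)) {
    mask <- states$masks[si]
    if (mask == 0L) next
    tab <- clado_events(mask, nA, states, j)
    keep <- !is.na(states$index[as.character(tab$left)]) &
            !is.na(states$index[as.character(tab$right)])
    clado[[si]] <- list(
      li = unname(states$index[as.character(tab$left[keep])]),
      ri = unname(states$index[as.character(tab$right[keep])]),
      w = tab$prob[keep] / sum(tab$prob[keep]),
      type = tab$type[keep])
  }
  clado
}

## Full setup: static pieces plus the generator, per-branch transition
## matrices and cladogenesis tables for one parameter vector.
dec_setup <- function(tree, coding, d, e, j, max_range_size,
                      dispersal_matrix = NULL, static = NULL) {
  if (d < 0 || e < 0 || j < 0 || j >= 1)
    stop("rates must satisfy d,e >= 0 and 0 <= j < 1", call. = FALSE)
  if (is.null(static))
    static <- dec_static(tree, coding, max_range_size, dispersal_matrix)
  nA <- length(static$areas)
  Q <- dec_generator(d, e, nA, static$states, static$dispersal_matrix)
  Pmats <- transition_matrices(Q, static$tree$edge.length)
  key <- sprintf("j%.17g", j)
  if (!is.null(static$cache) && !is.null(static$cache[[key]])) {
    clado <- static$cache[[key]]
  } else {
    clado <- dec_clado_tables(static$states, nA, j)
    if (!is.null(static$cache)) static$cache[[key]] <- clado
  }
  c(static, list(Q = Q, Pmats = Pmats, clado = clado))
}

## Pruning pass. Returns per-node conditional likelihood rows (rescaled),
## per-node log scalers, and per-edge "top" likelihoods
## D_child[x] = sum_y P(t)[x,y] L_child[y].
dec_prune <- function(su) {
  tree <- su$tree                       # already in postorder
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ns <- length(su$states$masks)
  L <- matrix(0, nn, ns)
  logscale <- numeric(nn)
  for (i in seq_len(ntip)) L[i, su$tip_state[i]] <- 1
  Dtop <- matrix(NA_real_, nn, ns)   # indexed by child node of each edge
  child_of <- vector("list", nn)

  for (ei in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[ei, 1]; child <- tree$edge[ei, 2]
    P <- lookup_P(su$Pmats, tree$edge.length[ei])
    Dtop[child, ] <- as.vector(P %*% L[child, ])
    child_of[[parent]] <- c(child_of[[parent]], child)
    if (length(child_of[[parent]]) == 2L) {
      ch <- child_of[[parent]]
      Dl <- Dtop[ch[1], ]; Dr <- Dtop[ch[2], ]
      for (si in seq_len(ns)) {
        tab <- su$clado[[si]]
        if (is.null(tab)) next                      # empty range: weight 0
        L[parent, si] <- sum(tab$w * Dl[tab$li] * Dr[tab$ri])
      }
      sc <- max(L[parent, ])
      if (sc <= 0) return(NULL)                     # impossible data
      L[parent, ] <- L[parent, ] / sc
      logscale[parent] <- log(sc) + sum(logscale[ch])
    }
  }
  list(tree = tree, L = L, logscale = logscale, Dtop = Dtop,
       children = child_of, root = ntip + 1L)
}

root_prior_vec <- function(su, root_range = NULL) {
  ns <- length(su$states$masks)
  prior <- numeric(ns)
  if (is.null(root_range)) {
    prior[su$states$masks != 0L] <- 1 / sum(su$states$masks != 0L)
  } else {
    prior[state_of(areas_to_mask(root_range, su$areas), su$states)] <- 1
  }
  prior
}

#' DEC / DEC+j log-likelihood
#'
#' Felsenstein pruning over the range state space (all non-empty area
#' subsets up to the maximum range size, plus the absorbing empty range):
#' anagenetic transitions by the exponential of the generator with per-area
#' gains at rate `d` (times the number of occupied source areas under the
#' default all-ones dispersal multiplier) and per-area losses at rate `e`;
#' at each node conditional likelihoods are combined over the allowed
#' cladogenetic events with equal weight per event, jump events taking total
#' weight `j` under DEC+j. The root prior is uniform over allowed non-empty
#' ranges unless a fixed `root_range` is given.
#'
#' @param tree dated bifurcating `phylo`.
#' @param coding a `range_coding` covering every tip.
#' @param d,e,j model parameters (`j = 0` gives plain DEC).
#' @param max_range_size maximum areas per range (default: all areas).
#' @param root_range optional fixed root range string.
#' @param dispersal_matrix optional areas x areas rate multiplier.
#' @param static precomputed parameter-independent setup (internal use,
#'   shared across evaluations when optimizing).
#' @return Log-likelihood (scalar; `-Inf` for impossible data).
#' @export
dec_loglik <- function(tree, coding, d, e, j = 0,
                       max_range_size = length(coding$areas),
                       root_range = NULL, dispersal_matrix = NULL,
                       static = NULL) {
  su <- dec_setup(tree, coding, d, e, j, max_range_size, dispersal_matrix,
                  static = static)
  pr <- dec_prune(su)
  if (is.null(pr)) return(-Inf)
  prior <- root_prior_vec(su, root_range)
  lik <- sum(prior * pr$L[pr$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[pr$root]
}

#' Fit a DEC or DEC+j model by maximum likelihood
#'
#' Bounded L-BFGS-B optimization of [dec_loglik()] over `(d, e)` (DEC) or
#' `(d, e, j)` (DEC+j). `AIC = 2 df - 2 lnL` with df = 2 (DEC) or 3 (DEC+j).
#'
#' @inheritParams dec_loglik
#' @param model `"DEC"` or `"DEC+j"`.
#' @param start optional starting values `c(d, e[, j])`.
#' @param control options passed to [stats::optim()] (merged over the
#'   defaults `factr = 1e11`, `maxit = 500`).
#' @return An object of class `dec_fit`: `model`, `d`, `e`, `j`, `loglik`,
#'   `df`, `aic`, `convergence`, `data_id`.
#' @export
fit_dec <- function(tree, coding, model = c("DEC", "DEC+j"),
                    max_range_size = length(coding$areas),
                    root_range = NULL, dispersal_matrix = NULL,
                    start = NULL, control = list()) {
  model <- match.arg(model)
  withj <- model == "DEC+j"
  if (is.null(start)) start <- if (withj) c(0.01, 0.01, 0.01)
                               else c(0.01, 0.01)
  static <- dec_static(tree, coding, max_range_size, dispersal_matrix)
  obj <- function(par) {
    -dec_loglik(tree, coding, d = par[1], e = par[2],
                j = if (withj) par[3] else 0,
                max_range_size = max_range_size, root_range = root_range,
                static = static)
  }
  lower <- c(1e-12, 1e-12, if (withj) 0)
  upper <- c(100, 100, if (withj) 0.999)
  ctrl <- utils::modifyList(list(factr = 1e11, maxit = 500), control)
  opt <- stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = ctrl)
  if (opt$convergence != 0)
    warning("DEC optimization did not converge cleanly (code ",
            opt$convergence, ")")
  df <- if (withj) 3L else 2L
  lnL <- -opt$value
  structure(list(model = model, d = opt$par[1], e = opt$par[2],
                 j = if (withj) opt$par[3] else 0,
                 loglik = lnL, df = df, aic = dec_aic(lnL, df),
                 convergence = opt$convergence,
                 max_range_size = max_range_size, root_range = root_range,
                 data_id = dec_data_id(tree, coding)),
            class = "dec_fit")
}

#' AIC from a log-likelihood and its degrees of freedom
#'
#' `AIC = 2 df - 2 lnL`, the identity under which fitted range-evolution
#' models are compared.
#'
#' @param loglik maximized log-likelihood.
#' @param df number of free parameters.
#' @return AIC value.
#' @export
dec_aic <- function(loglik, df) 2 * df - 2 * loglik

dec_data_id <- function(tree, coding) {
  paste(paste(sort(tree$tip.label), collapse = "|"),
        paste(coding$ranges[sort(names(coding$ranges))], collapse = "|"),
        sep = "::")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("<dec_fit> %s: lnL=%.6f d=%.6g e=%.3g j=%.3g AIC=%.6f\n",
              x$model, x$loglik, x$d, x$e, x$j, x$aic))
  invisible(x)
}

#' Rank fitted range-evolution models by AIC
#'
#' @param fits list of `dec_fit` objects on identical data.
#' @param tie_delta AIC difference under which models are flagged as
#'   statistically indistinguishable (default 2).
#' @return Data frame sorted by AIC with `model`, `loglik`, `df`, `d`, `e`,
#'   `j`, `aic`, `delta_aic`, `indistinguishable`.
#' @export
compare_models <- function(fits, tie_delta = 2) {
  if (inherits(fits, "dec_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "dec_fit")))
  ids <- vapply(fits, `[[`, "", "data_id")
  if (length(unique(ids)) > 1)
    stop("fits were made on different data", call. = FALSE)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, loglik = f$loglik, df = f$df, d = f$d,
               e = f$e, j = f$j, aic = f$aic)))
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$indistinguishable <- tab$delta_aic < tie_delta
  rownames(tab) <- NULL
  tab
}

#' Biogeographic stochastic mapping (BSM)
#'
#' Samples complete range-evolution histories conditional on the observed
#' tip ranges and the fitted parameters: node states are drawn from the
#' conditional-likelihood-weighted cladogenesis tables on a preorder pass,
#' and branch histories are drawn by exact endpoint-conditioned
#' uniformization of the anagenetic chain. Anagenetic dispersal events
#' (range expansions) are counted by source area -> gained area, a gain
#' being attributed fractionally (1/|range|) to each occupied source area;
#' cladogenetic jump dispersals are accumulated in a separate matrix.
#'
#' @param tree,coding as in [dec_loglik()].
#' @param fit a `dec_fit` (or list with `d`, `e`, `j`).
#' @param n_maps number of stochastic maps (default 1000).
#' @param seed integer seed.
#' @param max_range_size,root_range,dispersal_matrix as in [dec_loglik()].
#' @return An object of class `bsm_summary`: `dispersal` (mean anagenetic
#'   source x destination counts over maps), `jump` (mean cladogenetic jump
#'   counts), `event_totals` (mean per-event-type counts), `n_maps`, `seed`.
#' @export
bsm <- function(tree, coding, fit, n_maps = 1000, seed = 1L,
                max_range_size = length(coding$areas), root_range = NULL,
                dispersal_matrix = NULL) {
  su <- dec_setup(tree, coding, fit$d, fit$e, fit$j, max_range_size,
                  dispersal_matrix)
  pr <- dec_prune(su)
  if (is.null(pr)) stop("data impossible under the fitted model",
                        call. = FALSE)
  prior <- root_prior_vec(su, root_range)
  root_w <- prior * pr$L[pr$root, ]
  if (sum(root_w) <= 0) stop("zero root mass", call. = FALSE)

  tree <- pr$tree
  ntip <- length(tree$tip.label)
  nA <- length(su$areas)
  bits <- bitwShiftL(1L, seq_len(nA) - 1L)
  masks <- su$states$masks
  ## uniformization pieces
  Lam <- max(-diag(su$Q))
  Rm <- diag(nrow(su$Q)) + if (Lam > 0) su$Q / Lam else su$Q * 0
  edge_parent <- tree$edge[, 1]; edge_child <- tree$edge[, 2]
  preord <- rev(seq_len(nrow(tree$edge)))   # reverse postorder = preorder

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  disp_sum <- matrix(0, nA, nA, dimnames = list(su$areas, su$areas))
  jump_sum <- matrix(0, nA, nA, dimnames = list(su$areas, su$areas))
  type_names <- c("dispersal", "extinction", "sympatry", "subset",
                  "vicariance", "jump")
  totals <- stats::setNames(numeric(length(type_names)), type_names)

  for (map in seq_len(n_maps)) {
    node_state <- integer(ntip + tree$Nnode)
    top_state <- integer(ntip + tree$Nnode)   # state at top of edge to node
    node_state[pr$root] <- sample.int(length(masks), 1L, prob = root_w)
    disp <- matrix(0, nA, nA); jmp <- matrix(0, nA, nA)
    tl <- stats::setNames(numeric(length(type_names)), type_names)

    ## cladogenesis draws at nodes, branch paths along edges, in preorder
    sample_clado <- function(node) {
      si <- node_state[node]
      tab <- su$clado[[si]]
      ch <- pr$children[[node]]
      Dl <- pr$Dtop[ch[1], ]; Dr <- pr$Dtop[ch[2], ]
      w <- tab$w * Dl[tab$li] * Dr[tab$ri]
      k <- sample.int(length(w), 1L, prob = w)
      top_state[ch[1]] <<- tab$li[k]
      top_state[ch[2]] <<- tab$ri[k]
      tl[tab$type[k]] <<- tl[tab$type[k]] + 1
      if (tab$type[k] == "jump") {
        anc <- masks[si]
        dmask <- bitwAnd(bitwOr(masks[tab$li[k]], masks[tab$ri[k]]),
                         bitwNot(anc))
        dest <- which(bitwAnd(dmask, bits) > 0L)
        src <- which(bitwAnd(anc, bits) > 0L)
        for (sa in src) jmp[sa, dest] <<- jmp[sa, dest] + 1 / length(src)
      }
    }
    sample_clado(pr$root)
    for (ei in preord) {
      parent <- edge_parent[ei]; child <- edge_child[ei]
      a <- top_state[child]
      t_len <- tree$edge.length[ei]
      P <- lookup_P(su$Pmats, t_len)
      w <- P[a, ] * pr$L[child, ]
      y <- sample.int(length(masks), 1L, prob = w)
      node_state[child] <- y
      path <- sample_ctmc_path(a, y, t_len, P[a, y], Lam, Rm)
      if (length(path$from)) {
        for (s in seq_along(path$from)) {
          mfrom <- masks[path$from[s]]; mto <- masks[path$to[s]]
          if (popcount(mto) > popcount(mfrom)) {
            gained <- which(bitwAnd(mto - mfrom, bits) > 0L)
            src <- which(bitwAnd(mfrom, bits) > 0L)
            disp[src, gained] <- disp[src, gained] + 1 / length(src)
            tl["dispersal"] <- tl["dispersal"] + 1
          } else {
            tl["extinction"] <- tl["extinction"] + 1
          }
        }
      }
      if (child > ntip) sample_clado(child)
    }
    disp_sum <- disp_sum + disp
    jump_sum <- jump_sum + jmp
    totals <- totals + tl
  }
  structure(list(dispersal = disp_sum / n_maps, jump = jump_sum / n_maps,
                 event_totals = totals / n_maps, n_maps = n_maps,
                 seed = seed),
            class = "bsm_summary")
}

## Exact endpoint-conditioned CTMC path via uniformization. Returns the real
## (non-virtual) transitions as parallel vectors from/to (state indices).
sample_ctmc_path <- function(a, y, t_len, p_ay, Lam, Rm, max_n = 10000L) {
  if (Lam <= 0 || t_len <= 0) return(list(from = integer(0), to = integer(0)))
  ## draw number of uniformized jumps N | endpoints
  u <- stats::runif(1) * p_ay
  acc <- 0
  Rn <- diag(nrow(Rm))            # R^0
  powers <- list(Rn)
  n <- -1L
  repeat {
    n <- n + 1L
    if (n > 0) {
      Rn <- Rn %*% Rm
      powers[[n + 1L]] <- Rn
    }
    acc <- acc + stats::dpois(n, Lam * t_len) * powers[[n + 1L]][a, y]
    if (acc >= u || n >= max_n) break
  }
  if (n == 0L) return(list(from = integer(0), to = integer(0)))
  ## sample the uniformized state sequence given N = n
  z <- integer(n + 1L); z[1] <- a; z[n + 1L] <- y
  if (n > 1L) for (i in 2:n) {
    w <- Rm[z[i - 1L], ] * powers[[n - i + 2L]][, y]
    z[i] <- sample.int(length(w), 1L, prob = w)
  }
  real <- which(z[-1] != z[-(n + 1L)])
  list(from = z[real], to = z[real + 1L])
}

#' @export
print.bsm_summary <- function(x, ...) {
  cat("<bsm_summary> mean anagenetic dispersal counts over", x$n_maps,
      "maps:\n")
  print(round(x$dispersal, 3))
  if (any(x$jump > 0)) {
    cat("cladogenetic jump counts:\n"); print(round(x$jump, 3))
  }
  invisible(x)
}
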