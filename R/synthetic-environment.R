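#' Generate a synthetic environmental stack with an energy gradient
#'
#' Builds a set of co-registered environmental surfaces on a regular grid,
#' organised around a single "energy" peak: potential evapotranspiration
#' (PET, mm/yr) decays monotonically with distance from the peak, actual
#' evapotranspiration (AET, mm/yr) tracks PET, temperature seasonality (%)
#' increases away from the peak, and altitude (m) is unstructured. This is
#' the abstract stand-in for the empirical energy gradient (HANPP/PET/AET
#' and bioclim surfaces) that richness analyses assume.
#'
#' @param shape integer vector `c(rows, cols)`, both positive.
#' @param peak numeric vector `c(row, col)` giving the energy peak location
#'   (may be fractional; 1-based grid coordinates).
#' @param decay positive decay scale of the energy gradient, in cells; the
#'   deterministic part of PET is `pet_base + pet_range *
#'   exp(-dist^2 / (2 * decay^2))`.
#' @param cell_size cell edge length in degrees (metadata only).
#' @param noise_sd relative noise level: independent Gaussian noise with
#'   standard deviation `noise_sd` times each layer's deterministic range is
#'   added to every layer. Use 0 for exactly radially symmetric surfaces.
#' @param layers character vector of layers to generate; any subset of
#'   `c("PET", "AET", "temp_seasonality", "altitude")`. `"PET"` is the
#'   energy layer used by range placement.
#' @param seed integer seed; identical seeds give bit-identical stacks.
#'
#' @return An object of class `env_stack`: a list with `layers` (named list
#'   of numeric matrices), `shape`, `cell_size`, `peak`, `decay`.
#' @export
make_environment <- function(shape = c(20, 20), peak = shape / 2,
                             decay = max(shape) / 4, cell_size = 1,
                             noise_sd = 0.05,
                             layers = c("PET", "AET", "temp_seasonality",
                                        "altitude"),
                             seed = 1L) {
  if (length(shape) != 2 || any(shape < 1) || any(shape != round(shape)))
    stop("'shape' must be two positive integers", call. = FALSE)
  if (decay <= 0) stop("'decay' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  layers <- match.arg(layers, several.ok = TRUE)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dist2 <- (rows - peak[1])^2 + (cols - peak[2])^2
  kernel <- exp(-dist2 / (2 * decay^2))      # 1 at the peak, -> 0 far away

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  spec <- list(
    PET = list(base = 600, range = 1200, shape = kernel),
    AET = list(base = 400, range = 1100, shape = kernel),
    temp_seasonality = list(base = 2, range = 10, shape = 1 - kernel),
    altitude = list(base = 200, range = 400,
                    shape = matrix(0.5, nr, nc))
  )
  out <- list()
  for (nm in layers) {
    s <- spec[[nm]]
    layer <- s$base + s$range * s$shape
    if (noise_sd > 0)
      layer <- layer + matrix(stats::rnorm(nr * nc, 0, noise_sd * s$range),
                              nr, nc)
    out[[nm]] <- layer
  }
  structure(list(layers = out, shape = c(nr, nc), cell_size = cell_size,
                 peak = peak, decay = decay),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> ", x$shape[1], "x", x$shape[2], " cells of ",
      x$cell_size, " deg; layers: ", paste(names(x$layers), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

## Save and restore the caller's RNG so seeded generators do not perturb
## the global random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
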