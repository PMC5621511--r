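#' Build contiguity-based spatial weights on a grid's valid cells
#'
#' Queen (8-neighbour) or rook (4-neighbour) first-order contiguity among
#' the valid cells of a grid, in deterministic row-major cell order.
#'
#' @param grid a `richness_grid`, or a logical matrix giving the valid mask.
#' @param scheme `"queen"` or `"rook"`.
#' @param row_standardize divide each row of weights by its sum.
#' @param include_self give every cell a self-neighbour with weight 1
#'   (required by the Gi* statistic).
#' @return An object of class `spatial_weights`: `neighbors` and `weights`
#'   (lists, one entry per valid cell), `n`, `cells` (row/col index of each
#'   valid cell), `scheme`, `row_standardized`, `self_included`.
#' @export
build_weights <- function(grid, scheme = c("queen", "rook"),
                          row_standardize = FALSE, include_self = FALSE) {
  scheme <- match.arg(scheme)
  mask <- if (inherits(grid, "richness_grid")) grid$valid
          else if (is.logical(grid)) grid
          else !is.na(grid)
  nr <- nrow(mask); nc <- ncol(mask)
  valid_idx <- which(mask)                      # row-major within columns
  n <- length(valid_idx)
  if (n < 2) stop("need at least two valid cells", call. = FALSE)
  pos <- integer(nr * nc); pos[valid_idx] <- seq_len(n)

  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  k <- if (scheme == "rook") 4L else 8L
  r0 <- (valid_idx - 1L) %% nr + 1L
  c0 <- (valid_idx - 1L) %/% nr + 1L
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    rr <- r0[i] + dr[seq_len(k)]; cc <- c0[i] + dc[seq_len(k)]
    keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- pos[(cc[keep] - 1L) * nr + rr[keep]]
    nb <- sort(nb[nb > 0L])
    if (include_self) nb <- sort(c(i, nb))
    neighbors[[i]] <- nb
  }
  weights <- lapply(neighbors, function(nb) rep(1, length(nb)))
  if (row_standardize)
    weights <- lapply(weights, function(w) if (length(w)) w / sum(w) else w)
  structure(list(neighbors = neighbors, weights = weights, n = n,
                 cells = cbind(row = r0, col = c0), scheme = scheme,
                 row_standardized = row_standardize,
                 self_included = include_self),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> ", x$n, " sites, ", x$scheme, " contiguity",
      if (x$row_standardized) ", row-standardized",
      if (x$self_included) ", self-included", "\n", sep = "")
  invisible(x)
}

## Dense weight matrix (small-n convenience used internally and by tests).
weights_matrix <- function(W) {
  M <- matrix(0, W$n, W$n)
  for (i in seq_len(W$n)) M[i, W$neighbors[[i]]] <- W$weights[[i]]
  M
}

#' Global Moran's I with normal-theory or permutation inference
#'
#' `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `S0` the total weight; expectation under no autocorrelation is
#' `-1/(n-1)`. Positive significant I indicates clustering of like values.
#'
#' @param values numeric vector over the weight object's sites.
#' @param W a `spatial_weights` object (self-inclusion not allowed here).
#' @param inference `"normal"` (Cliff-Ord normality variance) or
#'   `"permutation"`.
#' @param n_perm permutations when `inference = "permutation"`.
#' @param seed seed for the permutation draw.
#' @return List with `I`, `expected`, `sd`, `z`, `p` (two-sided for normal
#'   inference; upper-tail Monte-Carlo p for permutation), `inference`.
#' @export
morans_i <- function(values, W, inference = c("normal", "permutation"),
                     n_perm = 999, seed = 1L) {
  inference <- match.arg(inference)
  stopifnot(inherits(W, "spatial_weights"))
  if (W$self_included)
    stop("Moran's I requires weights without self-inclusion", call. = FALSE)
  n <- W$n
  if (length(values) != n) stop("length(values) != number of sites",
                                call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  z <- values - mean(values)
  if (sum(z^2) == 0) stop("zero variance: Moran's I undefined", call. = FALSE)

  Wm <- weights_matrix(W)
  S0 <- sum(Wm)
  num <- as.numeric(t(z) %*% Wm %*% z)
  I <- (n / S0) * num / sum(z^2)
  EI <- -1 / (n - 1)

  if (inference == "normal") {
    S1 <- sum((Wm + t(Wm))^2) / 2
    S2 <- sum((rowSums(Wm) + colSums(Wm))^2)
    VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
    zscore <- (I - EI) / sqrt(VI)
    p <- 2 * stats::pnorm(-abs(zscore))
    list(I = I, expected = EI, sd = sqrt(VI), z = zscore, p = p,
         inference = "normal")
  } else {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    sims <- replicate(n_perm, {
      zp <- z[sample.int(n)]
      (n / S0) * as.numeric(t(zp) %*% Wm %*% zp) / sum(zp^2)
    })
    sd_sim <- stats::sd(sims)
    zscore <- (I - mean(sims)) / sd_sim
    p <- (sum(sims >= I) + 1) / (n_perm + 1)
    list(I = I, expected = EI, sd = sd_sim, z = zscore, p = p,
         inference = "permutation", null_sims = sims)
  }
}

#' Getis-Ord Gi* local hotspot statistic
#'
#' Per-cell Z score comparing the weighted sum of values in a cell-plus-
#' neighbourhood to its expectation under the global mean:
#' `Z_i = (sum_j w_ij x_j - xbar * sum_j w_ij) /
#'  (S * sqrt((n * sum_j w_ij^2 - (sum_j w_ij)^2) / (n - 1)))`
#' with `xbar` and `S` the global mean and population standard deviation.
#' Large positive Z marks cells embedded in high-value neighbourhoods.
#'
#' @param values numeric vector over the weight object's sites.
#' @param W a `spatial_weights` built with `include_self = TRUE`.
#' @return Numeric vector of per-cell Z scores.
#' @export
getis_ord_gstar <- function(values, W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (!W$self_included)
    stop("Gi* requires self-inclusive weights (include_self = TRUE)",
         call. = FALSE)
  n <- W$n
  if (n < 3) stop("need n >= 3 sites", call. = FALSE)
  if (length(values) != n) stop("length(values) != number of sites",
                                call. = FALSE)
  xbar <- mean(values)
  S <- sqrt(mean(values^2) - xbar^2)        # population form
  if (S == 0) stop("zero variance: Gi* undefined", call. = FALSE)
  z <- numeric(n)
  for (i in seq_len(n)) {
    w <- W$weights[[i]]; nb <- W$neighbors[[i]]
    sw <- sum(w); sw2 <- sum(w^2)
    num <- sum(w * values[nb]) - xbar * sw
    den <- S * sqrt((n * sw2 - sw^2) / (n - 1))
    z[i] <- num / den
  }
  z
}

#' Delineate statistically significant hotspot clusters from Gi* scores
#'
#' Cells with (optionally FDR-corrected) significant positive Z are flagged
#' and grouped into queen-connected clusters; significant negative cells
#' (coldspots) are reported separately.
#'
#' @param z per-cell Gi* Z scores, in the weight object's site order.
#' @param W the `spatial_weights` the scores were computed on (supplies the
#'   cell coordinates for the connectivity step).
#' @param alpha significance level (default 0.05).
#' @param correction `"fdr"` (Benjamini-Hochberg, default) or `"none"`.
#' @return An object of class `hotspot_result`: per-cell `z`, `p`
#'   (two-sided), `p_adj`, `hot` and `cold` flags, `cluster` labels (0 =
#'   none; positive integers label hotspot clusters, negative coldspot
#'   clusters), `cells`, and a `clusters` summary data frame (label,
#'   n_cells, max_z, mean_z, type).
#' @export
delineate_hotspots <- function(z, W, alpha = 0.05,
                               correction = c("fdr", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(W, "spatial_weights"), length(z) == W$n)
  if (!all(is.finite(z))) stop("Z scores must be finite", call. = FALSE)
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (correction == "fdr") stats::p.adjust(p, "BH") else p
  hot <- p_adj <= alpha & z > 0
  cold <- p_adj <= alpha & z < 0

  cluster <- integer(W$n)
  lab_cells <- function(flag, sign) {
    lab <- 0L
    todo <- which(flag)
    seen <- logical(W$n)
    for (s in todo) {
      if (seen[s]) next
      lab <- lab + 1L
      comp <- s; queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        i <- queue[1]; queue <- queue[-1]
        nb <- queen_cells(W$cells[i, 1], W$cells[i, 2], W$cells)
        nb <- nb[flag[nb] & !seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb); comp <- c(comp, nb)
      }
      cluster[comp] <<- sign * lab
    }
    lab
  }
  n_hot <- lab_cells(hot, 1L)
  n_cold <- lab_cells(cold, -1L)

  labs <- setdiff(sort(unique(cluster)), 0L)
  summ <- do.call(rbind, lapply(labs, function(l) {
    i <- which(cluster == l)
    data.frame(label = l, n_cells = length(i), max_z = max(abs(z[i])) *
                 sign(l), mean_z = mean(z[i]),
               type = if (l > 0) "hotspot" else "coldspot")
  }))
  if (is.null(summ))
    summ <- data.frame(label = integer(0), n_cells = integer(0),
                       max_z = numeric(0), mean_z = numeric(0),
                       type = character(0))
  structure(list(z = z, p = p, p_adj = p_adj, hot = hot, cold = cold,
                 cluster = cluster, cells = W$cells, clusters = summ,
                 alpha = alpha, correction = correction),
            class = "hotspot_result")
}

queen_cells <- function(r, c, cells) {
  which(abs(cells[, 1] - r) <= 1L & abs(cells[, 2] - c) <= 1L &
          !(cells[, 1] == r & cells[, 2] == c))
}

#' @export
print.hotspot_result <- function(x, ...) {
  nh <- sum(x$clusters$type == "hotspot")
  cat("<hotspot_result> ", nh, " hotspot cluster(s), ",
      sum(x$hot), " hot cells; ", sum(x$clusters$type == "coldspot"),
      " coldspot cluster(s) (alpha=", x$alpha, ", ", x$correction, ")\n",
      sep = "")
  invisible(x)
}
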