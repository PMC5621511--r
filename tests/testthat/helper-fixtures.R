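# Shared fixtures and independent brute-force oracles. The oracles are
# written as plainly as possible (explicit loops, no shared code with the
# package internals) so they can serve as references for the vectorized
# implementations.

## -- fixtures -------------------------------------------------------------

# 15 species x 40 sites template with heterogeneous row sums (4..28); only
# the row sums matter for the fixed-rows/equiprobable-columns null.
calibration_template <- function() {
  r <- round(seq(4, 28, length.out = 15))
  M <- matrix(0L, 15, 40)
  for (i in seq_along(r)) M[i, seq_len(r[i])] <- 1L
  M
}

# Small synthetic source-sink world shared across tests.
demo_world <- function(seed = 2, n_species = 50, shape = c(20, 20)) {
  env <- make_environment(shape = shape, peak = shape / 2, decay = 5,
                          noise_sd = 0.05, seed = seed)
  ranges <- make_ranges(n_species, env, seed = seed + 1000)
  list(env = env, ranges = ranges, grid = stack_richness(ranges),
       pam = build_matrix(ranges))
}

# Random binary matrix without empty rows (and optionally columns).
random_binary <- function(nr, nc, fill, no_empty_cols = FALSE) {
  M <- matrix(rbinom(nr * nc, 1, fill), nr, nc)
  for (i in which(rowSums(M) == 0)) M[i, sample.int(nc, 1)] <- 1L
  if (no_empty_cols)
    for (j in which(colSums(M) == 0)) M[sample.int(nr, 1), j] <- 1L
  storage.mode(M) <- "integer"
  M
}

# Dated random coalescent tree rescaled to a given root depth (Myr).
dated_tree <- function(ntip, depth = 25, seed = 1) {
  set.seed(seed)
  tr <- ape::rcoal(ntip)
  tr$edge.length <- tr$edge.length * depth /
    max(ape::node.depth.edgelength(tr))
  tr
}

## -- oracles --------------------------------------------------------------

# NODF by direct definition: loop over all row pairs and column pairs.
oracle_nodf <- function(M) {
  overlap <- function(hi, lo, lo_tot) sum(hi & lo) / lo_tot * 100
  pairs_sum <- function(A) {
    s <- 0
    for (i in seq_len(nrow(A) - 1)) for (k in (i + 1):nrow(A)) {
      ti <- sum(A[i, ]); tk <- sum(A[k, ])
      if (ti == tk || min(ti, tk) == 0) next
      if (ti > tk) s <- s + overlap(A[i, ] == 1, A[k, ] == 1, tk)
      else s <- s + overlap(A[k, ] == 1, A[i, ] == 1, ti)
    }
    s
  }
  nr <- nrow(M); nc <- ncol(M)
  rp <- nr * (nr - 1) / 2; cp <- nc * (nc - 1) / 2
  rs <- pairs_sum(M); cs <- pairs_sum(t(M))
  list(NODF = (rs + cs) / (rp + cp), NODFc = cs / cp, NODFr = rs / rp)
}

# C-score by triple loop over pairs and sites.
oracle_cscore <- function(M) {
  n <- nrow(M)
  cu <- c()
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    shared <- 0
    for (s in seq_len(ncol(M))) if (M[i, s] == 1 && M[k, s] == 1)
      shared <- shared + 1
    cu <- c(cu, (sum(M[i, ]) - shared) * (sum(M[k, ]) - shared))
  }
  mean(cu)
}

# Discrepancy by direct definition: order columns by decreasing totals
# (ties by descending lexicographic column content), then count presences
# outside each row's leftmost r_i slots.
oracle_discrepancy <- function(M) {
  tot <- colSums(M)
  keys <- apply(M, 2, paste, collapse = "")
  ord <- order(-tot, keys, method = "radix", decreasing = c(FALSE, TRUE))
  P <- M[, ord, drop = FALSE]
  br <- 0
  for (i in seq_len(nrow(P))) {
    r <- sum(P[i, ])
    if (r > 0) br <- br + r - sum(P[i, seq_len(r)])
  }
  br
}

# Matrix temperature by per-cell enumeration: pack with the same ordering
# rule, then recompute every cell's isocline crossing with uniroot and the
# scores from first principles.
oracle_temperature <- function(M) {
  P <- pack(M, tie_break = "content")$matrix
  fill <- mean(P)
  p <- uniroot(function(lp) {
    pp <- exp(lp)
    x <- seq(0, 1, length.out = 2049)
    f <- 1 - (1 - pmin(1, (1 - x)^pp))^(1 / pp)
    h <- x[2] - x[1]
    w <- rep(c(4, 2), length.out = length(x) - 2)
    h / 3 * (f[1] + f[length(f)] + sum(w * f[2:(length(f) - 1)])) - fill
  }, c(-12, 12), tol = 1e-12)$root
  p <- exp(p)
  nr <- nrow(P); nc <- ncol(P)
  u_obs <- 0; base <- 0; gains <- c()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    u <- (j - 0.5) / nc; v <- (i - 0.5) / nr
    g <- (1 - u)^p + (1 - v)^p - 1
    tmin <- max(-u, -v); tmax <- min(1 - u, 1 - v)
    ts <- uniroot(function(t) (1 - u - t)^p + (1 - v - t)^p - 1,
                  c(tmin, tmax), tol = 1e-14)$root
    sq <- (abs(ts) / (tmax - tmin))^2
    s1 <- if (g < 0) sq else 0      # unexpected presence score
    s0 <- if (g > 0) sq else 0      # unexpected absence score
    u_obs <- u_obs + (if (P[i, j] == 1) s1 else s0)
    base <- base + s0
    gains <- c(gains, s1 - s0)
  }
  n_cells <- nr * nc
  u_max <- (base + sum(sort(gains, decreasing = TRUE)[seq_len(sum(P))])) /
    n_cells
  100 * (u_obs / n_cells) / u_max
}

# Gi* by per-cell loop over an explicit neighbor structure.
oracle_gstar <- function(values, W) {
  n <- length(values)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    nb <- W$neighbors[[i]]; w <- W$weights[[i]]
    sw <- 0; sw2 <- 0; sx <- 0
    for (k in seq_along(nb)) {
      sw <- sw + w[k]; sw2 <- sw2 + w[k]^2
      sx <- sx + w[k] * values[nb[k]]
    }
    z[i] <- (sx - xbar * sw) / (S * sqrt((n * sw2 - sw^2) / (n - 1)))
  }
  z
}

# Moran's I by direct double loop.
oracle_morans_i <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  s0 <- 0; num <- 0
  for (i in seq_len(n)) {
    nb <- W$neighbors[[i]]; w <- W$weights[[i]]
    for (k in seq_along(nb)) {
      s0 <- s0 + w[k]
      num <- num + w[k] * z[i] * z[nb[k]]
    }
  }
  (n / s0) * num / sum(z^2)
}
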