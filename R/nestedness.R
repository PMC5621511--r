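#' Pack a presence-absence matrix
#'
#' Reorders rows by decreasing row totals (most frequent species on top) and
#' columns by decreasing column totals (richest sites on the left), or by a
#' decreasing external site score (e.g. AET) when one is supplied.
#'
#' @param M 0/1 matrix with no all-zero column.
#' @param criterion `"totals"` or `"external"`.
#' @param external_site_scores numeric vector of per-site scores, required
#'   when `criterion = "external"`.
#' @param tie_break `"stable"` (ties in totals keep original order, the
#'   default, reproducible display behaviour) or `"content"` (canonical:
#'   ties resolved by bipartite colour-refinement keys and descending
#'   lexicographic line content, making the packed matrix invariant to
#'   row/column permutations of the input; used internally by the
#'   temperature and discrepancy indices).
#' @return An object of class `packed_matrix`: `matrix` (the reordered
#'   matrix), `row_order`, `col_order` (permutations of the original
#'   indices), `criterion`.
#' @export
pack <- function(M, criterion = c("totals", "external"),
                 external_site_scores = NULL,
                 tie_break = c("stable", "content")) {
  criterion <- match.arg(criterion)
  tie_break <- match.arg(tie_break)
  M <- check_binary(M)
  if (criterion == "external") {
    if (is.null(external_site_scores) ||
        length(external_site_scores) != ncol(M))
      stop("'external_site_scores' must have one score per site",
           call. = FALSE)
    col_order <- order(-external_site_scores)
    row_order <- line_order(M, tie_break)
  } else if (tie_break == "stable") {
    col_order <- line_order(t(M), tie_break)
    row_order <- line_order(M, tie_break)
  } else if (!anyDuplicated(rowSums(M))) {
    ## tie-free rows are canonical by totals alone; columns then sort
    ## canonically by content against that fixed row order
    row_order <- order(-rowSums(M))
    col_order <- line_order(t(M[row_order, , drop = FALSE]), "content")
  } else if (!anyDuplicated(colSums(M))) {
    col_order <- order(-colSums(M))
    row_order <- line_order(M[, col_order, drop = FALSE], "content")
  } else {
    ## both margins tied: permutation-invariant packing via bipartite
    ## colour-refinement keys (start-independent), then alternating content
    ## passes against the progressively fixed other margin
    keys <- refined_line_keys(M)
    ro <- order(-rowSums(M), keys$row, method = "radix")
    P <- M[ro, , drop = FALSE]
    co <- line_order(t(P), "content")
    P <- P[, co, drop = FALSE]
    ro2 <- line_order(P, "content")
    P <- P[ro2, , drop = FALSE]
    co2 <- line_order(t(P), "content")
    row_order <- ro[ro2]
    col_order <- co[co2]
  }
  structure(list(matrix = M[row_order, col_order, drop = FALSE],
                 row_order = row_order, col_order = col_order,
                 criterion = criterion),
            class = "packed_matrix")
}

## Bipartite colour refinement: rows and columns start coloured by their
## totals; each pass recolours a line by its own colour plus the sorted
## multiset of colours of the lines it intersects. The keys are invariant
## to input permutations by construction; lines still tied afterwards are
## refinement-equivalent.
refined_line_keys <- function(M) {
  rk <- match(-rowSums(M), sort(unique(-rowSums(M))))
  ck <- match(-colSums(M), sort(unique(-colSums(M))))
  ## a line's refined signature is its colour-count profile over the other
  ## margin, hashed with fixed irrational weights: equal multisets give
  ## bit-identical sums (the counts are integers), distinct ones collide
  ## with negligible probability
  w <- sqrt(seq_len(nrow(M) + ncol(M)) + pi)
  recolor <- function(old, sig) {
    o <- order(old, sig)
    run <- cumsum(c(1L, (diff(old[o]) != 0) | (diff(sig[o]) != 0)))
    out <- integer(length(old)); out[o] <- run
    out
  }
  for (it in seq_len(8)) {
    if (!anyDuplicated(rk) && !anyDuplicated(ck)) break
    K <- max(rk); L <- max(ck)
    Rm <- matrix(0, K, nrow(M)); Rm[cbind(rk, seq_len(nrow(M)))] <- 1
    Cm <- matrix(0, L, ncol(M)); Cm[cbind(ck, seq_len(ncol(M)))] <- 1
    rsig <- as.vector(w[seq_len(L)] %*% (Cm %*% t(M)))
    csig <- as.vector(w[seq_len(K)] %*% (Rm %*% M))
    rk2 <- recolor(rk, rsig)
    ck2 <- recolor(ck, csig)
    stable <- max(rk2) == K && max(ck2) == L
    rk <- rk2; ck <- ck2
    if (stable) break
  }
  list(row = rk, col = ck)
}

## Order rows of M by decreasing totals; ties stable or by descending
## lexicographic content (given the CURRENT column order).
line_order <- function(M, tie_break) {
  tot <- rowSums(M)
  if (tie_break == "stable") return(order(-tot))
  ## content keys are only needed within groups of tied totals
  keys <- character(nrow(M))
  tied <- which(tot %in% unique(tot[duplicated(tot)]))
  if (length(tied))
    keys[tied] <- apply(M[tied, , drop = FALSE], 1, paste, collapse = "")
  order(-tot, keys, method = "radix", decreasing = c(FALSE, TRUE))
}

check_binary <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (!all(M %in% c(0, 1))) stop("matrix must be 0/1", call. = FALSE)
  storage.mode(M) <- "integer"
  M
}

#' @export
print.packed_matrix <- function(x, ...) {
  cat("<packed_matrix> ", nrow(x$matrix), "x", ncol(x$matrix),
      ", criterion=", x$criterion, "\n", sep = "")
  invisible(x)
}

#' NODF nestedness metric
#'
#' For every ordered pair of lines with strictly decreasing marginal totals,
#' the paired overlap is the percentage of the sparser line's presences also
#' present in the fuller line; pairs with equal totals contribute 0. `NODFr`
#' averages row pairs, `NODFc` column pairs, and `NODF` all pairs. Range
#' 0-100, larger = more nested. Order-invariant: only marginal totals are
#' compared, so no packing is needed.
#'
#' @param M 0/1 matrix, at least 2 x 2, no all-zero row or column.
#' @return List with `NODF`, `NODFc`, `NODFr`.
#' @export
nodf <- function(M) {
  M <- check_binary(M)
  if (nrow(M) < 2 || ncol(M) < 2) stop("need >= 2 rows and columns",
                                       call. = FALSE)
  if (any(rowSums(M) == 0)) stop("matrix has an all-zero row", call. = FALSE)
  row_part <- nodf_pairs(M)
  col_part <- nodf_pairs(t(M))
  list(NODF = 100 * (row_part$sum + col_part$sum) /
         (row_part$n_pairs + col_part$n_pairs),
       NODFc = 100 * col_part$sum / col_part$n_pairs,
       NODFr = 100 * row_part$sum / row_part$n_pairs)
}

## Sum of paired-overlap fractions over all unordered row pairs of M.
## Pairs with equal totals contribute 0; an empty (all-zero) line also
## contributes 0, the convention needed so the index is defined on null
## replicates whose column totals may drop to zero.
nodf_pairs <- function(M) {
  tot <- rowSums(M)
  S <- M %*% t(M)                       # shared presences
  n <- nrow(M)
  lo <- outer(tot, tot, pmin)
  ok <- outer(tot, tot, "!=") & lo > 0
  contrib <- matrix(0, n, n)
  contrib[ok] <- S[ok] / lo[ok]
  list(sum = sum(contrib[upper.tri(contrib)]), n_pairs = n * (n - 1) / 2)
}

#' Matrix temperature (nestedness)
#'
#' Departure of the packed matrix from the fill isocline of a perfectly
#' nested matrix with the same fill, on a 0-100 scale (0 = perfectly
#' nested). The matrix is packed internally (rows and columns by decreasing
#' totals, ties broken by line content so the index is permutation
#' invariant) and each cell is mapped to the unit square with the top-left
#' corner at the origin. The isocline is the symmetric power curve
#' `(1-u)^p + (1-v)^p = 1` whose sub-curve area equals the fill (the
#' standard fill-line family of the temperature literature; `p = 1`
#' reproduces the straight diagonal at 50% fill). Presences outside the
#' curve and absences inside it are unexpected and score the squared
#' distance to the isocline along the cell's (1,1) diagonal, normalized by
#' that diagonal's in-square length. The mean unexpectedness is scaled
#' against the maximum attainable for a matrix of the same shape and fill,
#' so T lies exactly in `[0, 100]`.
#'
#' @param M 0/1 matrix with fill strictly between 0 and 1.
#' @return Temperature T in `[0, 100]`.
#' @export
temperature <- function(M) {
  M <- check_binary(M)
  fill <- mean(M)
  if (fill == 0 || fill == 1)
    stop("temperature undefined at 0% or 100% fill", call. = FALSE)
  P <- pack(M, tie_break = "content")$matrix
  sc <- temperature_cell_scores(P)
  u_obs <- mean(ifelse(P == 1L, sc$if_present, sc$if_absent))
  ## maximal disorder with the same presence count: take the base score of
  ## an all-absent matrix and add the largest per-cell gains from presence
  gain <- sort(as.vector(sc$if_present - sc$if_absent), decreasing = TRUE)
  u_max <- (sum(sc$if_absent) + sum(gain[seq_len(sum(P))])) / length(P)
  100 * u_obs / u_max
}

## Per-cell unexpectedness scores of a packed matrix: the score a cell would
## contribute if it held a presence (`if_present`: nonzero outside the
## isocline) and if it held an absence (`if_absent`: nonzero inside it).
## Re-derived independently by the enumeration oracle in the tests.
temperature_cell_scores <- function(P) {
  nr <- nrow(P); nc <- ncol(P)
  p <- isocline_p(mean(P))
  u <- as.vector((col(P) - 0.5) / nc)
  v <- as.vector((row(P) - 0.5) / nr)
  gval <- (1 - u)^p + (1 - v)^p - 1       # > 0 inside (presence expected)
  ## the (1,1) diagonal through (u,v) spans t in [tmin, tmax]; the isocline
  ## crossing h(t) = (1-u-t)^p + (1-v-t)^p - 1 = 0 is unique because h is
  ## strictly decreasing, with h(tmin) >= 0 >= h(tmax)
  tmin <- pmax(-u, -v); tmax <- pmin(1 - u, 1 - v)
  ## initial guess by inverting phi(s) = v_iso(s) - s (strictly decreasing)
  ## on a precomputed grid, then Newton polish to machine precision
  grid <- isocline_grid(p)
  s0 <- stats::approx(grid$phi, grid$s, xout = v - u, rule = 2)$y
  tstar <- pmin(pmax(s0 - u, tmin), tmax)
  for (iter in 1:4) {
    a <- 1 - u - tstar; b <- 1 - v - tstar
    h <- a^p + b^p - 1
    hp <- -p * (a^(p - 1) + b^(p - 1))
    tstar <- pmin(pmax(tstar - h / pmin(hp, -1e-300), tmin), tmax)
  }
  sq <- (abs(tstar) / (tmax - tmin))^2    # (d / D)^2; sqrt(2) cancels
  dim(sq) <- dim(gval) <- dim(P)
  list(if_present = sq * (gval < 0),
       if_absent = sq * (gval > 0))
}

## Exponent p such that the area under the isocline (1-u)^p + (1-v)^p = 1
## within the unit square equals the fill (memoised: null replicates share
## the observed matrix's fill).
.iso_cache <- new.env(parent = emptyenv())
isocline_p <- function(fill) {
  key <- sprintf("%.15g", fill)
  hit <- .iso_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- exp(stats::uniroot(function(lp) isocline_area(exp(lp)) - fill,
                          c(-12, 12), tol = 1e-12)$root)
  .iso_cache[[key]] <- p
  p
}

## Tabulated phi(s) = v_iso(s) - s used to seed the per-cell Newton solve.
isocline_grid <- function(p) {
  key <- sprintf("grid%.15g", p)
  hit <- .iso_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- seq(0, 1, length.out = 4097)
  viso <- 1 - (1 - pmin(1, (1 - s)^p))^(1 / p)
  out <- list(s = s, phi = viso - s)
  .iso_cache[[key]] <- out
  out
}

## Area of {(u,v): (1-u)^p + (1-v)^p > 1} by Simpson integration of
## v(u) = 1 - (1 - (1-u)^p)^(1/p).
isocline_area <- function(p) {
  x <- seq(0, 1, length.out = 2049)
  f <- 1 - (1 - pmin(1, (1 - x)^p))^(1 / p)
  h <- x[2] - x[1]
  w <- rep(c(4, 2), length.out = length(x) - 2)
  h / 3 * (f[1] + f[length(f)] + sum(w * f[2:(length(f) - 1)]))
}

#' Brualdi-Sanderson discrepancy (BR)
#'
#' With columns ordered by decreasing totals, BR is the number of presences
#' lying outside each row's leftmost `r_i` positions (`r_i` = row total),
#' i.e. the minimum number of presence shifts needed to reach the maximally
#' packed matrix with the same row sums. Ties in column totals are broken by
#' the canonical content rule of [pack()] so the index does not depend on
#' the input row/column order.
#'
#' @param M 0/1 matrix.
#' @return Non-negative integer discrepancy.
#' @export
discrepancy <- function(M) {
  M <- check_binary(M)
  P <- pack(M, tie_break = "content")$matrix   # row order does not matter
  r <- rowSums(P)
  br <- 0L
  for (i in seq_len(nrow(P))) {
    if (r[i] > 0)
      br <- br + r[i] - sum(P[i, seq_len(r[i])])
  }
  as.integer(br)
}

#' Fixed-rows / equiprobable-columns null model
#'
#' Each replicate keeps every species' occurrence count (row total) exactly
#' and places its presences uniformly at random without replacement among
#' all sites, so column totals vary freely with every site equiprobable.
#'
#' @param M 0/1 matrix (template supplying the row sums and dimensions).
#' @param n_iter number of replicates.
#' @param seed integer seed; the ensemble is reproducible.
#' @return List of `n_iter` randomized 0/1 matrices.
#' @export
null_fixed_rows_equiprob_cols <- function(M, n_iter, seed = 1L) {
  M <- check_binary(M)
  if (n_iter < 1) stop("'n_iter' must be >= 1", call. = FALSE)
  r <- rowSums(M)
  if (any(r > ncol(M)))
    stop("row total exceeds the number of columns", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  replicate(n_iter, random_fixed_rows(r, ncol(M)), simplify = FALSE)
}

random_fixed_rows <- function(r, nc) {
  out <- matrix(0L, length(r), nc)
  for (i in seq_along(r))
    if (r[i] > 0) out[i, sample.int(nc, r[i])] <- 1L
  out
}

#' Monte-Carlo nestedness test under the fixed-rows/equiprobable-columns null
#'
#' Computes the observed index, the null mean and percentile 95% CI over
#' `n_iter` randomizations, and the one-tailed Monte-Carlo p-value in the
#' nested direction (smaller is more nested for T and BR; larger for the
#' NODF family), with the (count + 1)/(n_iter + 1) correction. The p-value
#' for the opposite tail is reported too, and results in which the
#' significant tail opposes the nested direction are flagged rather than
#' resolved.
#'
#' @param M 0/1 matrix.
#' @param index one of `"T"`, `"BR"`, `"NODF"`, `"NODFc"`, `"NODFr"`.
#' @param n_iter number of null replicates (default 10000).
#' @param seed integer seed.
#' @return An object of class `nestedness_result`: `index`, `observed`,
#'   `null_mean`, `ci` (percentile 2.5/97.5%), `p` (nested tail),
#'   `p_opposite`, `tail` (`"less"` for T/BR, `"greater"` for NODF),
#'   `direction_conflict`, `n_iter`, `seed`.
#' @export
nestedness_test <- function(M, index = c("NODF", "T", "BR", "NODFc", "NODFr"),
                            n_iter = 10000, seed = 1L) {
  index <- match.arg(index)
  M <- check_binary(M)
  f <- index_fun(index)
  obs <- f(M)
  r <- rowSums(M)
  if (any(r > ncol(M)))
    stop("row total exceeds the number of columns", call. = FALSE)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  null_vals <- numeric(n_iter)
  for (b in seq_len(n_iter)) null_vals[b] <- f(random_fixed_rows(r, ncol(M)))

  tail <- if (index %in% c("T", "BR")) "less" else "greater"
  if (tail == "less") {
    p <- (sum(null_vals <= obs) + 1) / (n_iter + 1)
    p_opp <- (sum(null_vals >= obs) + 1) / (n_iter + 1)
  } else {
    p <- (sum(null_vals >= obs) + 1) / (n_iter + 1)
    p_opp <- (sum(null_vals <= obs) + 1) / (n_iter + 1)
  }
  nested_side <- if (tail == "less") obs < mean(null_vals)
                 else obs > mean(null_vals)
  structure(list(index = index, observed = obs,
                 null_mean = mean(null_vals),
                 ci = stats::quantile(null_vals, c(0.025, 0.975),
                                      names = FALSE),
                 p = p, p_opposite = p_opp, tail = tail,
                 direction_conflict = (!nested_side) && p_opp <= 0.05,
                 n_iter = n_iter, seed = seed),
            class = "nestedness_result")
}

index_fun <- function(index) {
  switch(index,
         T = temperature,
         BR = function(M) as.numeric(discrepancy(M)),
         NODF = function(M) nodf(M)$NODF,
         NODFc = function(M) nodf(M)$NODFc,
         NODFr = function(M) nodf(M)$NODFr)
}

#' @export
print.nestedness_result <- function(x, ...) {
  cat(sprintf(
    "<nestedness_result> %s obs=%.4g null=%.4g (CI %.4g-%.4g) p=%.4g (%s)%s\n",
    x$index, x$observed, x$null_mean, x$ci[1], x$ci[2], x$p, x$tail,
    if (x$direction_conflict) " [DIRECTION CONFLICT]" else ""))
  invisible(x)
}
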