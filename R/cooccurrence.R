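#' Checkerboard C-score
#'
#' For each unordered species pair (i, j) the number of checkerboard units
#' is `CU_ij = (r_i - S_ij)(r_j - S_ij)` with `r` the row totals and `S_ij`
#' the number of shared sites; the C-score is the mean CU over all pairs.
#' Larger values indicate more segregated (checkerboarded) co-occurrence.
#'
#' @param M 0/1 species-by-sites matrix with at least two rows.
#' @return Mean checkerboard units (numeric scalar).
#' @export
c_score <- function(M) {
  M <- check_binary(M)
  n <- nrow(M)
  if (n < 2) stop("need at least two species (rows)", call. = FALSE)
  r <- rowSums(M)
  S <- M %*% t(M)
  D <- r - S                      # D[i,j] = r_i - S_ij (r recycled by column)
  CU <- D * t(D)                  # (r_i - S_ij)(r_j - S_ij)
  mean(CU[upper.tri(CU)])
}

#' Standardized effect size
#'
#' `SES = (observed - null mean) / null standard deviation`. Negative values
#' indicate more co-occurrence (aggregation) than expected under the null;
#' positive values indicate segregation. With approximately normal
#' deviations, about 95% of SES values fall in `[-2, 2]` under the null.
#'
#' @param observed observed index value.
#' @param null_mean,null_sd mean and standard deviation of the null
#'   distribution (`null_sd > 0`).
#' @return The standardized effect size.
#' @export
ses <- function(observed, null_mean, null_sd) {
  if (!is.finite(null_sd) || null_sd <= 0)
    stop("'null_sd' must be positive", call. = FALSE)
  (observed - null_mean) / null_sd
}

#' C-score co-occurrence test under fixed-rows/equiprobable-columns nulls
#'
#' Compares the observed C-score with its distribution over `n_null`
#' randomized matrices generated by the same fixed-rows/equiprobable-columns
#' algorithm used for the nestedness tests, and reports the standardized
#' effect size and Monte-Carlo p-values for both tails. The null variance is
#' reported in population form (divisor `n_null`).
#'
#' @param M 0/1 species-by-sites matrix.
#' @param n_null number of null matrices (default 50000).
#' @param seed integer seed.
#' @return An object of class `cscore_result`: `observed`, `null_mean`,
#'   `null_variance`, `null_sd`, `ses`, `p_less`, `p_greater` (Monte-Carlo,
#'   +1 corrected), `n_null`, `seed`.
#' @export
cooccurrence_test <- function(M, n_null = 50000, seed = 1L) {
  M <- check_binary(M)
  obs <- c_score(M)
  r <- rowSums(M)
  if (any(r > ncol(M)))
    stop("row total exceeds the number of columns", call. = FALSE)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  nulls <- numeric(n_null)
  for (b in seq_len(n_null)) nulls[b] <- c_score(random_fixed_rows(r, ncol(M)))

  mu <- mean(nulls)
  v <- mean((nulls - mu)^2)              # population variance
  structure(list(observed = obs, null_mean = mu, null_variance = v,
                 null_sd = sqrt(v), ses = ses(obs, mu, sqrt(v)),
                 p_less = (sum(nulls <= obs) + 1) / (n_null + 1),
                 p_greater = (sum(nulls >= obs) + 1) / (n_null + 1),
                 n_null = n_null, seed = seed),
            class = "cscore_result")
}

#' @export
print.cscore_result <- function(x, ...) {
  cat(sprintf(paste0("<cscore_result> C-score=%.4g null mean=%.4g ",
                     "variance=%.4g SES=%.4g (p_less=%.4g, p_greater=%.4g, ",
                     "%d nulls)\n"),
              x$observed, x$null_mean, x$null_variance, x$ses, x$p_less,
              x$p_greater, x$n_null))
  invisible(x)
}
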