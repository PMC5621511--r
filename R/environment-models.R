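#' Assemble a per-site table of richness and environmental covariates
#'
#' One row per valid (occupied) grid cell: longitude, latitude (cell-centre
#' coordinates in the grid's own degree units, origin at the north-west
#' corner), species richness, and every layer of the environmental stack.
#'
#' @param grid a `richness_grid`.
#' @param env an `env_stack` co-registered with the grid.
#' @return A data frame (one row per valid cell).
#' @export
site_table <- function(grid, env) {
  stopifnot(inherits(grid, "richness_grid"), inherits(env, "env_stack"))
  if (!identical(grid$shape, env$shape))
    stop("grid and environment are not co-registered", call. = FALSE)
  idx <- which(grid$valid)
  r <- (idx - 1L) %% grid$shape[1] + 1L
  c <- (idx - 1L) %/% grid$shape[1] + 1L
  out <- data.frame(longitude = (c - 0.5) * grid$cell_size,
                    latitude = -(r - 0.5) * grid$cell_size,
                    richness = grid$richness[idx])
  for (nm in names(env$layers)) out[[nm]] <- env$layers[[nm]][idx]
  out
}

#' Pearson correlation with a t-based two-tailed p-value
#'
#' @param x,y numeric vectors (n >= 3, both with positive variance).
#' @return List with `rho` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y))
    stop("need n >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}

## Small-sample corrected AIC; k counts all estimated parameters including
## the intercept and the error variance (k = attr(logLik, "df") for lm).
aicc_lm <- function(fit) {
  n <- stats::nobs(fit)
  k <- attr(stats::logLik(fit), "df")
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Forward-stepwise OLS selection under AICc
#'
#' Starting from the intercept-only model, greedily adds the candidate
#' covariate giving the largest AICc decrease, stopping when no addition
#' decreases AICc. Selected covariates are reported ordered by decreasing
#' absolute standardized coefficient. Ties in AICc decrease are broken by
#' candidate order in `candidates`.
#'
#' @param sites data frame (e.g. from [site_table()]).
#' @param response name of the response column (default `"richness"`).
#' @param candidates character vector of candidate covariate names.
#' @return An object of class `model_fit`: `family = "OLS"`, `selected`
#'   (ordered), `coefficients` data frame (term, estimate, std_coeff,
#'   std_error, p), `r_squared`, `aicc`, `fit` (the `lm` object).
#' @export
forward_stepwise <- function(sites, response = "richness", candidates) {
  stopifnot(is.data.frame(sites), length(candidates) >= 1,
            all(c(response, candidates) %in% names(sites)))
  X <- as.matrix(sites[candidates])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop <- candidates[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop("collinear candidate columns: ", paste(drop, collapse = ", "),
         call. = FALSE)
  }
  selected <- character(0)
  current <- stats::lm(stats::reformulate("1", response), data = sites)
  best_aicc <- aicc_lm(current)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(v) {
      f <- stats::reformulate(c(selected, v), response)
      aicc_lm(stats::lm(f, data = sites))
    }, 0)
    if (min(trial) >= best_aicc) break
    pick <- remaining[which.min(trial)]     # which.min: first = tie-break
    selected <- c(selected, pick)
    best_aicc <- min(trial)
  }
  f <- stats::reformulate(if (length(selected)) selected else "1", response)
  fit <- stats::lm(f, data = sites)
  make_model_fit(fit, sites, response, selected, "OLS",
                 r2 = summary(fit)$r.squared, aicc = aicc_lm(fit))
}

make_model_fit <- function(fit, sites, response, selected, family, r2, aicc,
                           extra = list()) {
  cf <- summary(fit)$coefficients
  sdy <- stats::sd(sites[[response]])
  std <- vapply(rownames(cf), function(term) {
    if (term == "(Intercept)") 0
    else cf[term, 1] * stats::sd(sites[[term]]) / sdy
  }, 0)
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      std_coeff = std, std_error = cf[, 2], p = cf[, 4],
                      row.names = NULL)
  ord <- order(-abs(coefs$std_coeff))
  ord <- c(which(coefs$term == "(Intercept)"),
           setdiff(ord, which(coefs$term == "(Intercept)")))
  coefs <- coefs[ord, , drop = FALSE]
  sel <- setdiff(coefs$term, "(Intercept)")
  structure(c(list(family = family, selected = sel, coefficients = coefs,
                   r_squared = r2, aicc = aicc, fit = fit), extra),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", x$family, ": ", paste(x$selected, collapse = " + "),
      sprintf("; R2=%.3f AICc=%.2f", x$r_squared, x$aicc),
      if (!is.null(x$lambda)) sprintf(" lambda=%.3f", x$lambda), "\n",
      sep = "")
  invisible(x)
}

#' Spatial autoregressive (SAR) model by maximum likelihood
#'
#' Default is the spatial-error form `y = X beta + u`, `u = lambda W u + eps`
#' fitted by profile maximum likelihood over `lambda`, with the
#' log-determinant computed from the spectrum of the row-standardized
#' contiguity matrix (real, via the symmetric similarity transform). The
#' spatial-lag form `y = lambda W y + X beta + eps` is available behind
#' `variant = "lag"`. Reported `r_squared` is the squared Pearson
#' correlation of trend-fitted versus observed values (a pseudo-R2).
#'
#' @param sites data frame of response and covariates.
#' @param covariates character vector of covariate names.
#' @param W row-standardized `spatial_weights` over the rows of `sites`.
#' @param response response column name.
#' @param variant `"error"` (default) or `"lag"`.
#' @return A `model_fit` with `family = "SAR"`, plus `lambda`, `lambda_se`,
#'   `loglik`.
#' @export
sar_fit <- function(sites, covariates, W, response = "richness",
                    variant = c("error", "lag")) {
  variant <- match.arg(variant)
  stopifnot(inherits(W, "spatial_weights"))
  if (!W$row_standardized)
    stop("SAR requires row-standardized weights", call. = FALSE)
  n <- nrow(sites)
  if (W$n != n) stop("weights do not match the site table", call. = FALSE)
  y <- sites[[response]]
  X <- cbind(`(Intercept)` = 1, as.matrix(sites[covariates]))
  Wm <- weights_matrix(W)

  ## spectrum of row-standardized W equals that of the symmetric
  ## D^{-1/2} B D^{-1/2}, hence real
  B <- (Wm > 0) * 1
  deg <- rowSums(B)
  Bs <- B / sqrt(outer(deg, deg))
  om <- eigen(Bs, symmetric = TRUE, only.values = TRUE)$values
  lo <- 1 / min(om) + 1e-6
  hi <- 1 / max(om) - 1e-6

  prof <- function(lambda) {
    A <- diag(n) - lambda * Wm
    if (variant == "error") {
      ys <- A %*% y; Xs <- A %*% X
      b <- qr.solve(Xs, ys)
      res <- ys - Xs %*% b
    } else {
      ys <- A %*% y
      b <- qr.solve(X, ys)
      res <- ys - X %*% b
    }
    s2 <- sum(res^2) / n
    sum(log(1 - lambda * om)) - n / 2 * (log(2 * pi * s2) + 1)
  }
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lambda <- opt$maximum
  loglik <- opt$objective
  h <- min(1e-4, (hi - lo) / 100)
  curv <- (prof(lambda + h) - 2 * loglik + prof(lambda - h)) / h^2
  lambda_se <- if (curv < 0) sqrt(-1 / curv) else NA_real_

  A <- diag(n) - lambda * Wm
  if (variant == "error") {
    ys <- A %*% y; Xs <- A %*% X
    b <- drop(qr.solve(Xs, ys))
    res <- ys - Xs %*% b
    s2 <- sum(res^2) / n
    vcv <- s2 * solve(crossprod(Xs))
    trend <- drop(X %*% b)
  } else {
    ys <- A %*% y
    b <- drop(qr.solve(X, ys))
    res <- ys - X %*% b
    s2 <- sum(res^2) / n
    vcv <- s2 * solve(crossprod(X))
    trend <- drop(X %*% b)
  }
  se <- sqrt(diag(vcv))
  zval <- b / se
  pr2 <- stats::cor(trend, y)^2
  k <- length(b) + 2                      # beta + lambda + sigma2
  aicc <- -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)

  cf <- data.frame(term = names(b), estimate = b,
                   std_coeff = vapply(names(b), function(t)
                     if (t == "(Intercept)") 0
                     else b[t] * stats::sd(sites[[t]]) / stats::sd(y), 0),
                   std_error = se, p = 2 * stats::pnorm(-abs(zval)),
                   row.names = NULL)
  structure(list(family = "SAR", variant = variant, selected = covariates,
                 coefficients = cf, r_squared = pr2, aicc = aicc,
                 lambda = lambda, lambda_se = lambda_se, loglik = loglik),
            class = "model_fit")
}

#' Linear quantile regression by check-loss minimization
#'
#' Fits `y = a + b x` minimizing the check loss at quantile `tau`. The
#' intercept is profiled out (for fixed slope the optimal intercept is a
#' type-1 tau-quantile of the residuals), leaving a convex one-dimensional
#' problem in the slope solved by Brent search.
#'
#' @param x,y numeric vectors.
#' @param tau quantile in (0, 1).
#' @return List with `intercept`, `slope`, `tau`, `loss`.
#' @export
rq_line <- function(x, y, tau) {
  if (tau <= 0 || tau >= 1) stop("'tau' must be in (0,1)", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate x", call. = FALSE)
  check_loss <- function(r) sum(r * (tau - (r < 0)))
  profile_b <- function(b) {
    r <- y - b * x
    a <- stats::quantile(r, tau, type = 1, names = FALSE)
    check_loss(r - a)
  }
  b_ols <- stats::cov(x, y) / stats::var(x)
  span <- 10 * (abs(b_ols) + stats::sd(y) / stats::sd(x)) + 1
  opt <- stats::optimize(profile_b, c(b_ols - span, b_ols + span),
                         tol = 1e-10)
  b <- opt$minimum
  a <- stats::quantile(y - b * x, tau, type = 1, names = FALSE)
  list(intercept = a, slope = b, tau = tau, loss = opt$objective)
}

#' Quantile-regression constraint envelope with rank-score inference
#'
#' Fits linear quantile regressions at the requested extreme quantiles
#' (default 1st and 99th) to characterize the lower and upper constraints on
#' `y` over `x`, and tests each slope against zero with a seeded
#' permutation version of the quantile rank-score test: under the null the
#' scores `tau - 1[y < q_tau(y)]` are exchangeable against `x`, and the
#' statistic `sum (x - xbar) * score` is re-drawn over `n_boot` random
#' permutations. Pearson correlation for the same pair is reported
#' alongside.
#'
#' @param x,y numeric vectors (a warning is given below n = 30).
#' @param taus quantiles to fit (default `c(0.01, 0.99)`).
#' @param n_boot randomizations for the rank-score test (default 10000).
#' @param seed integer seed.
#' @return An object of class `quantile_envelope`: data frame `fits` (tau,
#'   intercept, slope, p), `pearson` (`rho`, `p`), `n_boot`, `seed`.
#' @export
quantile_envelope <- function(x, y, taus = c(0.01, 0.99), n_boot = 10000,
                              seed = 1L) {
  n <- length(x)
  if (n < 30)
    warning("fewer than 30 observations: extreme quantile fits are unstable")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  xc <- x - mean(x)
  fits <- lapply(taus, function(tau) {
    f <- rq_line(x, y, tau)
    q0 <- stats::quantile(y, tau, type = 1, names = FALSE)
    sc <- tau - (y < q0)
    t_obs <- sum(xc * sc)
    t_null <- replicate(n_boot, sum(xc * sc[sample.int(n)]))
    p <- (sum(abs(t_null) >= abs(t_obs)) + 1) / (n_boot + 1)
    data.frame(tau = tau, intercept = f$intercept, slope = f$slope, p = p)
  })
  structure(list(fits = do.call(rbind, fits),
                 pearson = pearson(x, y), n_boot = n_boot, seed = seed),
            class = "quantile_envelope")
}

#' @export
print.quantile_envelope <- function(x, ...) {
  cat("<quantile_envelope> rho=", round(x$pearson$rho, 3), "\n", sep = "")
  print(x$fits, row.names = FALSE)
  invisible(x)
}
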