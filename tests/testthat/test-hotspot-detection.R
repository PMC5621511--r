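test_that("contiguity weights have the textbook neighbour counts", {
  mask <- matrix(TRUE, 5, 5)
  Wq <- build_weights(mask, "queen")
  Wr <- build_weights(mask, "rook")
  # site order is row-major within columns; (3,3) is interior
  interior <- which(Wq$cells[, 1] == 3 & Wq$cells[, 2] == 3)
  expect_length(Wq$neighbors[[interior]], 8)
  expect_length(Wr$neighbors[[interior]], 4)
  corner <- which(Wq$cells[, 1] == 1 & Wq$cells[, 2] == 1)
  expect_length(Wr$neighbors[[corner]], 2)
  expect_length(Wq$neighbors[[corner]], 3)
  Ws <- build_weights(mask, "queen", include_self = TRUE)
  expect_true(all(vapply(seq_len(Ws$n), function(i)
    i %in% Ws$neighbors[[i]], TRUE)))
  Wst <- build_weights(mask, "queen", row_standardize = TRUE)
  expect_true(all(abs(vapply(Wst$weights, sum, 0) - 1) < 1e-12))
  expect_error(build_weights(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)),
               "two valid")
})

test_that("Moran's I is -1 on a perfect rook checkerboard", {
  v <- outer(1:6, 1:6, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  W <- build_weights(matrix(TRUE, 6, 6), "rook")
  # build values in the weights' site order
  vals <- v[cbind(W$cells[, 1], W$cells[, 2])]
  mi <- morans_i(vals, W)
  expect_equal(mi$I, -1, tolerance = 1e-12)
  expect_lt(mi$p, 0.05)
  expect_equal(mi$expected, -1 / (36 - 1))
})

test_that("Moran's I matches the loop oracle and is affine invariant", {
  set.seed(31)
  for (rep in 1:5) {
    mask <- matrix(runif(49) < 0.85, 7, 7)
    if (sum(mask) < 5) next
    W <- build_weights(mask, sample(c("queen", "rook"), 1))
    x <- rnorm(W$n)
    expect_equal(morans_i(x, W)$I, oracle_morans_i(x, W), tolerance = 1e-12)
    expect_equal(morans_i(3 + 2 * x, W)$I, morans_i(x, W)$I,
                 tolerance = 1e-12)
  }
  W <- build_weights(matrix(TRUE, 4, 4))
  expect_error(morans_i(rep(1, 16), W), "variance")
})

test_that("permuted surfaces give Moran's I centred on -1/(n-1)", {
  set.seed(32)
  mask <- matrix(TRUE, 20, 20)
  W <- build_weights(mask)
  x <- rnorm(400)
  mi <- morans_i(x, W, inference = "permutation", n_perm = 999, seed = 7)
  se <- sd(mi$null_sims) / sqrt(length(mi$null_sims))
  expect_lt(abs(mean(mi$null_sims) - (-1 / 399)), 3 * se)
  # permutation inference is seeded
  mi2 <- morans_i(x, W, inference = "permutation", n_perm = 999, seed = 7)
  expect_identical(mi$p, mi2$p)
})

test_that("Gi* matches a hand-computed corner case and the loop oracle", {
  # 3x3 grid, value 9 at the centre, queen + self: for the (1,1) corner the
  # neighbourhood is {(1,1),(1,2),(2,1),(2,2)}, so sum wx = 9, sum w = 4,
  # xbar = 1, S = sqrt(8), Z = (9 - 4) / (sqrt(8) sqrt((9*4 - 16)/8))
  #   = 5 / sqrt(20)
  vals9 <- rep(0, 9); vals9[5] <- 9      # centre in column-major order
  W <- build_weights(matrix(TRUE, 3, 3), "queen", include_self = TRUE)
  z <- getis_ord_gstar(vals9, W)
  corner <- which(W$cells[, 1] == 1 & W$cells[, 2] == 1)
  expect_equal(z[corner], 5 / sqrt(20), tolerance = 1e-10)
  set.seed(33)
  for (rep in 1:5) {
    mask <- matrix(runif(64) < 0.9, 8, 8)
    Wr <- build_weights(mask, "queen", include_self = TRUE)
    x <- rpois(Wr$n, 6)
    if (sd(x) == 0) next
    expect_equal(getis_ord_gstar(x, Wr), oracle_gstar(x, Wr),
                 tolerance = 1e-10)
  }
  expect_error(getis_ord_gstar(rep(2, W$n), W), "variance")
  Wns <- build_weights(matrix(TRUE, 3, 3))
  expect_error(getis_ord_gstar(vals9, Wns), "self")
})

test_that("Gi* peaks at a single spike for any contiguity scheme", {
  for (scheme in c("queen", "rook")) {
    W <- build_weights(matrix(TRUE, 9, 9), scheme, include_self = TRUE)
    x <- rep(0, W$n)
    spike <- which(W$cells[, 1] == 5 & W$cells[, 2] == 5)
    x[spike] <- 10
    z <- getis_ord_gstar(x, W)
    # binary weights tie the spike with its immediate neighbours, so the
    # spike attains (possibly shares) the maximum
    expect_equal(z[spike], max(z))
    expect_true(all(z[-c(spike, W$neighbors[[spike]])] < z[spike]))
  }
})

test_that("hotspot delineation flags, labels and summarizes consistently", {
  W <- build_weights(matrix(TRUE, 10, 10), "queen", include_self = TRUE)
  z <- rnorm(100, 0, 0.1)                 # nothing significant
  hs <- delineate_hotspots(z, W)
  expect_equal(nrow(hs$clusters), 0)
  expect_true(all(hs$cluster == 0))
  # all clustered cells are significant, each in exactly one cluster
  w <- demo_world(seed = 12)
  Wg <- build_weights(w$grid, include_self = TRUE)
  zg <- getis_ord_gstar(w$grid$richness[w$grid$valid], Wg)
  hs <- delineate_hotspots(zg, Wg)
  expect_true(all(hs$cluster[hs$hot] > 0))
  expect_true(all(hs$cluster[!hs$hot & !hs$cold] == 0))
  expect_equal(sum(hs$clusters$n_cells[hs$clusters$type == "hotspot"]),
               sum(hs$hot))
  # deterministic
  expect_identical(hs, delineate_hotspots(zg, Wg))
  # uncorrected inference is available and flags at least as many cells
  hs_raw <- delineate_hotspots(zg, Wg, correction = "none")
  expect_gte(sum(hs_raw$hot), sum(hs$hot))
})
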