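test_that("packing sorts by totals with documented tie handling", {
  tri <- matrix(c(1L, 1L, 1L, 1L, 1L, 0L, 1L, 0L, 0L), 3, 3, byrow = TRUE)
  pk <- pack(tri)
  expect_identical(pk$row_order, 1:3)
  expect_identical(pk$col_order, 1:3)
  # reversing a packed matrix then packing recovers the packed form
  rev_pk <- pack(tri[3:1, 3:1])
  expect_identical(rev_pk$matrix, tri)
  # stable tie-break: equal totals keep input order
  tied <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  expect_identical(pack(tied)$row_order, 1:2)
  expect_identical(pack(tied)$matrix, tied)
  # external ordering overrides column totals
  M <- matrix(c(1, 1, 1, 0, 1, 0), 2, 3)
  pe <- pack(M, criterion = "external",
             external_site_scores = c(1, 5, 3))
  expect_identical(pe$col_order, c(2L, 3L, 1L))
  expect_error(pack(M, criterion = "external",
                    external_site_scores = c(1, 2)), "per site")
})

test_that("NODF hits its boundary cases", {
  tri <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(nodf(tri)$NODF, 100)
  expect_equal(nodf(diag(2L))$NODF, 0)    # all totals equal
  expect_error(nodf(matrix(c(1, 0, 0, 0), 2, 2)), "all-zero row")
  expect_error(nodf(matrix(1, 1, 3)), "2 rows")
})

test_that("NODF equals the brute-force all-pairs oracle", {
  set.seed(41)
  for (rep in 1:30) {
    M <- random_binary(8, 8, runif(1, 0.2, 0.7))
    mine <- nodf(M)
    ref <- oracle_nodf(M)
    expect_equal(mine$NODF, ref$NODF, tolerance = 1e-12)
    expect_equal(mine$NODFc, ref$NODFc, tolerance = 1e-12)
    expect_equal(mine$NODFr, ref$NODFr, tolerance = 1e-12)
  }
})

test_that("NODF agrees with vegan on random matrices", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (rep in 1:20) {
    M <- random_binary(9, 12, runif(1, 0.25, 0.6), no_empty_cols = TRUE)
    vg <- vegan::nestednodf(M, order = TRUE, weighted = FALSE)$statistic
    expect_equal(nodf(M)$NODF, unname(vg["NODF"]), tolerance = 1e-8)
  }
})

test_that("temperature is 0 for isocline-perfect matrices and high for
           checkerboards", {
  tri <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(temperature(tri), 0)
  stair <- matrix(0L, 6, 8)
  for (i in 1:6) stair[i, seq_len(9 - i - 2)] <- 1L
  expect_lt(temperature(stair), 3)
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2L)
  expect_gt(temperature(cb), 40)
  expect_lt(temperature(cb), 100 + 1e-9)
  expect_error(temperature(matrix(1, 3, 3)), "fill")
  expect_error(temperature(matrix(0, 3, 3)), "fill")
})

test_that("temperature matches the cell-enumeration oracle", {
  set.seed(43)
  for (rep in 1:10) {
    M <- random_binary(6, 9, runif(1, 0.2, 0.7))
    expect_equal(temperature(M), oracle_temperature(M), tolerance = 1e-10)
  }
  # one displaced presence scores exactly its enumerated distance
  M <- matrix(c(1, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(temperature(M), oracle_temperature(M), tolerance = 1e-10)
})

test_that("discrepancy counts misplaced presences after packing", {
  tri <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  expect_identical(discrepancy(tri), 0L)
  # 2x2 identity: both single-shift options cost exactly one move
  expect_identical(discrepancy(diag(2L)), 1L)
  set.seed(44)
  for (rep in 1:30) {
    M <- random_binary(7, 10, runif(1, 0.2, 0.6))
    br <- discrepancy(M)
    # the oracle uses the plain decreasing-totals ordering, identical to the
    # canonical one whenever column totals are untied
    if (length(unique(colSums(M))) == ncol(M))
      expect_identical(br, as.integer(oracle_discrepancy(M)))
    expect_lte(br, sum(M))
  }
})

test_that("discrepancy agrees with vegan when column totals are unique", {
  skip_if_not_installed("vegan")
  set.seed(45)
  hits <- 0; tries <- 0
  while (hits < 10 && tries < 5000) {
    tries <- tries + 1
    M <- random_binary(15, 7, runif(1, 0.3, 0.6))
    if (length(unique(colSums(M))) != ncol(M)) next
    hits <- hits + 1
    expect_equal(discrepancy(M),
                 unname(vegan::nesteddisc(M)$statistic))
  }
  expect_gte(hits, 10)
})

test_that("indices are invariant to row and column permutations", {
  set.seed(46)
  M <- random_binary(8, 12, 0.4)
  for (rep in 1:5) {
    Mp <- M[sample(nrow(M)), sample(ncol(M))]
    expect_equal(nodf(Mp)$NODF, nodf(M)$NODF, tolerance = 1e-12)
    expect_equal(temperature(Mp), temperature(M), tolerance = 1e-10)
    expect_identical(discrepancy(Mp), discrepancy(M))
  }
})

test_that("more packed matrices are never hotter or more discrepant", {
  # move a displaced presence into its packed slot: T and BR cannot increase
  base <- matrix(0L, 5, 8)
  for (i in 1:5) base[i, seq_len(7 - i)] <- 1L
  worse <- base
  worse[5, 2] <- 0L; worse[5, 8] <- 1L    # displace one presence
  expect_lte(temperature(base), temperature(worse))
  expect_lte(discrepancy(base), discrepancy(worse))
})

test_that("the fixed-rows/equiprobable-columns null preserves row sums", {
  M <- calibration_template()
  nulls <- null_fixed_rows_equiprob_cols(M, 200, seed = 3)
  expect_length(nulls, 200)
  for (b in c(1, 50, 200))
    expect_identical(rowSums(nulls[[b]]), rowSums(M))
  expect_identical(null_fixed_rows_equiprob_cols(M, 5, seed = 9),
                   null_fixed_rows_equiprob_cols(M, 5, seed = 9))
})

test_that("null column totals are equiprobable across sites", {
  M <- calibration_template()
  nulls <- null_fixed_rows_equiprob_cols(M, 4000, seed = 11)
  col_means <- rowMeans(vapply(nulls, colSums, numeric(ncol(M))))
  p <- rowSums(M) / ncol(M)
  expected <- sum(p)
  se <- sqrt(sum(p * (1 - p)) / length(nulls))
  expect_true(all(abs(col_means - expected) < 4.5 * se))
})

test_that("nestedness_test reports coherent Monte-Carlo summaries", {
  w <- demo_world(seed = 3, n_species = 25, shape = c(12, 12))
  for (ix in c("T", "BR", "NODF", "NODFc", "NODFr")) {
    res <- nestedness_test(w$pam, ix, n_iter = 150, seed = 5)
    expect_gt(res$p, 0); expect_lte(res$p, 1)
    expect_lte(res$ci[1], res$null_mean)
    expect_gte(res$ci[2], res$null_mean)
    expect_identical(res$tail, if (ix %in% c("T", "BR")) "less"
                     else "greater")
  }
  a <- nestedness_test(w$pam, "NODF", n_iter = 100, seed = 8)
  b <- nestedness_test(w$pam, "NODF", n_iter = 100, seed = 8)
  expect_identical(a, b)
})

test_that("a strongly nested source-sink world is detected by all indices", {
  w <- demo_world(seed = 2)
  for (ix in c("T", "BR", "NODF")) {
    res <- nestedness_test(w$pam, ix, n_iter = 1000, seed = 13)
    expect_lt(res$p, 0.001)
    expect_false(res$direction_conflict)
  }
})

test_that("energy-ordered packing reuses the same machinery", {
  w <- demo_world(seed = 7, n_species = 15, shape = c(10, 10))
  aet <- site_table(w$grid, w$env)$AET
  pk <- pack(w$pam, criterion = "external", external_site_scores = aet)
  expect_identical(pk$col_order, order(-aet))
  # indices are order-invariant, so the energy ordering changes display
  # only, not the statistics
  expect_equal(nodf(pk$matrix)$NODF, nodf(w$pam)$NODF, tolerance = 1e-12)
})
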