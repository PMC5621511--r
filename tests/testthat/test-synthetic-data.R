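test_that("energy surface peaks where requested and decays symmetrically", {
  env <- make_environment(shape = c(10, 10), peak = c(5, 5), decay = 3,
                          noise_sd = 0, seed = 1)
  pet <- env$layers$PET
  expect_equal(which.max(pet), (5 - 1) * 10 + 5)  # column-major index (5,5)
  # cells equidistant from the peak carry identical energy
  expect_equal(pet[5, 8], pet[8, 5])
  expect_equal(pet[2, 5], pet[5, 2])
  expect_equal(pet[4, 4], pet[6, 6])
  # monotone decay with distance along a row
  expect_true(all(diff(pet[5, 5:10]) < 0))
})

test_that("environment generation is deterministic and validates inputs", {
  a <- make_environment(shape = c(8, 9), noise_sd = 0.1, seed = 42)
  b <- make_environment(shape = c(8, 9), noise_sd = 0.1, seed = 42)
  expect_identical(a, b)
  expect_error(make_environment(shape = c(0, 5)), "shape")
  expect_error(make_environment(decay = -1), "decay")
})

test_that("range sizes honour the requested distribution and bounds", {
  env <- make_environment(shape = c(10, 10), noise_sd = 0, seed = 1)
  one <- make_ranges(1, env, size_distribution = function(n) rep(1, n),
                     seed = 3)
  g <- stack_richness(one)
  expect_equal(sum(g$richness), 1)
  expect_equal(max(g$richness), 1)
  full <- make_ranges(5, env, size_distribution = function(n) rep(100, n),
                      seed = 3)
  expect_true(all(stack_richness(full)$richness == 5))
  expect_error(make_ranges(2, env, size_distribution = function(n)
    rep(101, n), seed = 1), "sizes")
  fixed <- make_ranges(20, env, size_distribution = function(n)
    rep(7, n), seed = 9)
  expect_true(all(fixed$sizes == 7))
  expect_true(all(vapply(fixed$occupancy, sum, 0) == 7))
})

test_that("ranges are single rook-connected patches", {
  env <- make_environment(shape = c(12, 12), seed = 5)
  rs <- make_ranges(20, env, seed = 6)
  for (occ in rs$occupancy) {
    idx <- which(occ)
    seen <- idx[1]
    frontier <- idx[1]
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, macrorich:::rook_neighbors,
                                 nr = 12, nc = 12)))
      nb <- setdiff(intersect(nb, idx), seen)
      seen <- c(seen, nb)
      frontier <- nb
    }
    expect_equal(sort(seen), sort(idx))
  }
})

test_that("peaked placement concentrates richness at the energy peak", {
  env <- make_environment(shape = c(20, 20), peak = c(10, 10), decay = 5,
                          noise_sd = 0, seed = 1)
  rs <- make_ranges(50, env, seed = 2)
  g <- stack_richness(rs)
  top <- which(g$richness == max(g$richness), arr.ind = TRUE)
  d <- sqrt((top[, 1] - 10)^2 + (top[, 2] - 10)^2)
  expect_true(min(d) <= 5)   # richest cell within one decay scale
  # and the surface is significantly autocorrelated
  W <- build_weights(g)
  mi <- morans_i(g$richness[g$valid], W)
  expect_gt(mi$I, 0)
  expect_lt(mi$p, 0.05)
})

test_that("range generation is reproducible under a seed", {
  env <- make_environment(shape = c(10, 10), seed = 1)
  expect_identical(make_ranges(10, env, seed = 4),
                   make_ranges(10, env, seed = 4))
})

test_that("a frozen DEC process leaves every tip at the root range", {
  tr <- dated_tree(8, depth = 10, seed = 2)
  # single-area root: the only allowed cladogenesis is sympatric copying,
  # so with d = e = j = 0 the range can never change
  h <- simulate_dec(tr, d = 0, e = 0, j = 0, areas = c("A", "B", "C"),
                    root_range = "B", seed = 1)
  expect_true(all(h$tip_ranges == "B"))
  expect_false(any(h$events$type %in% c("dispersal", "extinction")))
})

test_that("overwhelming extinction is flagged, not silently continued", {
  tr <- dated_tree(6, depth = 10, seed = 3)
  h <- simulate_dec(tr, d = 0, e = 50, j = 0, areas = c("A", "B"),
                    root_range = "A", seed = 1, resample = FALSE)
  expect_true(h$extinct)
  expect_error(simulate_dec(tr, d = 0, e = 50, j = 0, areas = c("A", "B"),
                            root_range = "A", seed = 1, max_attempts = 5),
               "extinction")
})

test_that("replaying the event log reproduces the tip ranges", {
  tr <- dated_tree(15, depth = 20, seed = 4)
  for (s in 1:5) {
    h <- simulate_dec(tr, d = 0.08, e = 0.02, j = 0.05,
                      areas = c("A", "B", "C", "D"), root_range = "B",
                      seed = s)
    expect_identical(replay_history(h), h$tip_ranges)
  }
  expect_identical(
    simulate_dec(tr, 0.05, 0.01, 0, c("A", "B"), "A", seed = 7)$events,
    simulate_dec(tr, 0.05, 0.01, 0, c("A", "B"), "A", seed = 7)$events)
})

test_that("mean dispersal count matches the two-area expectation", {
  # In a two-area system with e = 0 the range size k follows 1 -> 2 at rate
  # d (the dispersal event) and is absorbed at 2. At cladogenesis a
  # widespread parent leaves a single-area daughter with probability 2/3
  # (2 vicariance + 4 subset events, half of the subset daughters single).
  # Expected dispersal count = sum over edges of P(size 1 at edge top) *
  # (1 - exp(-d t)), propagated from the root.
  tr <- dated_tree(20, depth = 25, seed = 5)
  d <- 0.03
  tree <- reorder(tr, "cladewise")
  heights <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  p1 <- rep(NA_real_, ntip + tree$Nnode)
  p1[ntip + 1] <- 1                      # root range is single-area
  expected <- 0
  for (ei in seq_len(nrow(tree$edge))) {
    par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    p1_top <- p1[par] * 1 + (1 - p1[par]) * (2 / 3)
    t_len <- tree$edge.length[ei]
    expected <- expected + p1_top * (1 - exp(-d * t_len))
    p1[ch] <- p1_top * exp(-d * t_len)
  }
  counts <- vapply(1:1000, function(s) {
    h <- simulate_dec(tr, d = d, e = 0, j = 0, areas = c("A", "B"),
                      root_range = "A", seed = s)
    sum(h$events$type == "dispersal")
  }, 0)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 2 * se)
})
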