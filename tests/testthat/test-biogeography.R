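test_that("a frozen two-tip cherry concentrates mass on the shared area", {
  tr <- ape::read.tree(text = "(t1:1,t2:1);")
  cod <- range_coding(c("t1", "t2"), c("A", "A"), c("A", "B"))
  # no movement possible: likelihood = root-prior mass on {A} (3 allowed
  # non-empty ranges over two areas)
  expect_equal(dec_loglik(tr, cod, 0, 0, 0), log(1 / 3), tolerance = 1e-12)
  # with a fixed root at A the mass is 1
  expect_equal(dec_loglik(tr, cod, 0, 0, 0, root_range = "A"), 0,
               tolerance = 1e-12)
  # frozen tips in different single areas are reachable only by vicariance
  # from a root at {AB}: prior 1/3 times the one matching ordered pair of
  # the six cladogenetic events
  cod2 <- range_coding(c("t1", "t2"), c("A", "B"), c("A", "B"))
  expect_equal(dec_loglik(tr, cod2, 0, 0, 0), log(1 / 18),
               tolerance = 1e-12)
  # but impossible when the root is pinned to a single area
  expect_identical(dec_loglik(tr, cod2, 0, 0, 0, root_range = "A"), -Inf)
})

test_that("DEC likelihood matches an enumeration + matrix-exponential oracle", {
  # Two areas: states (empty, A, B, AB). The oracle builds the 4-state
  # generator explicitly, exponentiates branches with Matrix::expm, applies
  # the cladogenesis table by hand, and sums over root states.
  oracle_2area <- function(tree, tips, d, e) {
    states <- c("0", "A", "B", "AB")
    Q <- matrix(0, 4, 4, dimnames = list(states, states))
    Q["A", "AB"] <- d; Q["B", "AB"] <- d
    Q["A", "0"] <- e;  Q["B", "0"] <- e
    Q["AB", "A"] <- e; Q["AB", "B"] <- e
    diag(Q) <- -rowSums(Q)
    Pt <- function(t) as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
    # cladogenesis: from A -> (A,A); from B -> (B,B); from AB six equally
    # likely ordered pairs: (AB,A),(A,AB),(AB,B),(B,AB),(A,B),(B,A)
    clado <- list(
      A = list(pairs = list(c("A", "A")), w = 1),
      B = list(pairs = list(c("B", "B")), w = 1),
      AB = list(pairs = list(c("AB", "A"), c("A", "AB"), c("AB", "B"),
                             c("B", "AB"), c("A", "B"), c("B", "A")),
                w = rep(1 / 6, 6)))
    tipvec <- function(range) { v <- rep(0, 4); names(v) <- states
                                v[range] <- 1; v }
    Ldown <- function(node) {
      if (node <= length(tree$tip.label))
        return(tipvec(tips[tree$tip.label[node]]))
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      DL <- Pt(tree$edge.length[tree$edge[, 2] == kids[1]]) %*% Ldown(kids[1])
      DR <- Pt(tree$edge.length[tree$edge[, 2] == kids[2]]) %*% Ldown(kids[2])
      L <- rep(0, 4); names(L) <- states
      for (s in c("A", "B", "AB")) {
        tab <- clado[[s]]
        for (k in seq_along(tab$pairs))
          L[s] <- L[s] + tab$w[k] * DL[tab$pairs[[k]][1], 1] *
            DR[tab$pairs[[k]][2], 1]
      }
      L
    }
    root <- length(tree$tip.label) + 1
    log(mean(Ldown(root)[c("A", "B", "AB")]))
  }
  tr2 <- ape::read.tree(text = "(t1:2.0,t2:3.5);")
  tr3 <- ape::read.tree(text = "((t1:1.2,t2:0.8):1.5,t3:2.7);")
  for (tipset in list(c(t1 = "A", t2 = "B", t3 = "AB"),
                      c(t1 = "AB", t2 = "A", t3 = "A"),
                      c(t1 = "B", t2 = "B", t3 = "A"))) {
    for (par in list(c(0.05, 0), c(0.2, 0.04), c(0.01, 0.3))) {
      cod2 <- range_coding(c("t1", "t2"), tipset[1:2], c("A", "B"))
      expect_equal(dec_loglik(tr2, cod2, par[1], par[2]),
                   oracle_2area(tr2, tipset[1:2], par[1], par[2]),
                   tolerance = 1e-8)
      cod3 <- range_coding(c("t1", "t2", "t3"), tipset, c("A", "B"))
      expect_equal(dec_loglik(tr3, cod3, par[1], par[2]),
                   oracle_2area(tr3, tipset, par[1], par[2]),
                   tolerance = 1e-8)
    }
  }
})

test_that("small-d transition mass approximates d*t for a single branch", {
  # per-branch expected gains in a 2-area system: P(A -> AB over t) ~ d*t
  states <- macrorich:::dec_states(2, 2)
  for (dt in c(0.01, 0.005)) {
    Q <- macrorich:::dec_generator(dt, 0, 2, states)
    P <- macrorich:::transition_matrices(Q, 1)[[1]]
    iA <- macrorich:::state_of(1L, states)
    iAB <- macrorich:::state_of(3L, states)
    # exact mass is 1 - exp(-d t) = d t (1 - d t / 2 + ...): within 1%
    expect_equal(P[iA, iAB], dt, tolerance = 0.01)
  }
})

test_that("DEC+j at j = 0 collapses to plain DEC", {
  set.seed(71)
  for (rep in 1:3) {
    tr <- dated_tree(12, depth = 20, seed = 70 + rep)
    h <- simulate_dec(tr, 0.05, 0.01, 0, c("A", "B", "C"), "B",
                      seed = 70 + rep)
    cod <- range_coding(names(h$tip_ranges), h$tip_ranges, c("A", "B", "C"))
    expect_equal(dec_loglik(tr, cod, 0.07, 0.02, j = 0),
                 dec_loglik(tr, cod, 0.07, 0.02, j = 1e-300),
                 tolerance = 1e-10)
  }
})

test_that("the likelihood is invariant to consistent area relabeling", {
  tr <- dated_tree(10, depth = 15, seed = 72)
  h <- simulate_dec(tr, 0.06, 0.01, 0, c("A", "B", "C"), "A", seed = 5)
  cod <- range_coding(names(h$tip_ranges), h$tip_ranges, c("A", "B", "C"))
  relabel <- c(A = "C", B = "A", C = "B")
  swapped <- vapply(h$tip_ranges, function(r) {
    paste(sort(relabel[strsplit(r, "")[[1]]]), collapse = "")
  }, "")
  cod_sw <- range_coding(names(swapped), swapped, c("A", "B", "C"))
  expect_equal(dec_loglik(tr, cod, 0.04, 0.02, 0.1),
               dec_loglik(tr, cod_sw, 0.04, 0.02, 0.1), tolerance = 1e-10)
})

test_that("AIC identity and model ranking behave as defined", {
  expect_equal(dec_aic(-10, 2), 24)
  tr <- dated_tree(12, depth = 20, seed = 73)
  h <- simulate_dec(tr, 0.08, 0.01, 0, c("A", "B"), "A", seed = 3)
  cod <- range_coding(names(h$tip_ranges), h$tip_ranges, c("A", "B"))
  f1 <- fit_dec(tr, cod, "DEC", control = list(factr = 1e12))
  f2 <- fit_dec(tr, cod, "DEC+j", control = list(factr = 1e12))
  expect_equal(f1$aic, 2 * 2 - 2 * f1$loglik)
  expect_equal(f2$df, 3L)
  tab <- compare_models(list(f1, f2))
  expect_equal(tab$delta_aic[1], 0)
  expect_true(!is.unsorted(tab$aic))
  # DEC is nested in DEC+j, so its lnL cannot exceed DEC+j's (up to
  # optimization tolerance)
  expect_gte(f2$loglik, f1$loglik - 0.02)
  # single fit gives a trivial table; different data are rejected
  expect_equal(nrow(compare_models(f1)), 1)
  h2 <- simulate_dec(tr, 0.08, 0.01, 0, c("A", "B"), "B", seed = 99)
  cod2 <- range_coding(names(h2$tip_ranges), h2$tip_ranges, c("A", "B"))
  if (!identical(cod2$ranges, cod$ranges)) {
    f3 <- fit_dec(tr, cod2, "DEC", control = list(factr = 1e12))
    expect_error(compare_models(list(f1, f3)), "different data")
  }
})

test_that("BSM on an immobile clade yields an all-zero dispersal matrix", {
  tr <- dated_tree(8, depth = 10, seed = 74)
  tips <- setNames(rep("A", 8), tr$tip.label)
  cod <- range_coding(names(tips), tips, c("A", "B"))
  fit <- list(d = 1e-12, e = 1e-12, j = 0)
  bs <- bsm(tr, cod, fit, n_maps = 25, seed = 2)
  expect_true(all(bs$dispersal == 0))
  expect_true(all(bs$jump == 0))
  expect_identical(bs, bsm(tr, cod, fit, n_maps = 25, seed = 2))
})

test_that("conditional likelihood rows stay properly scaled", {
  tr <- dated_tree(15, depth = 20, seed = 75)
  h <- simulate_dec(tr, 0.05, 0.01, 0, c("A", "B", "C", "D"), "B", seed = 6)
  cod <- range_coding(names(h$tip_ranges), h$tip_ranges,
                      c("A", "B", "C", "D"))
  su <- macrorich:::dec_setup(tr, cod, 0.05, 0.01, 0, 4)
  pr <- macrorich:::dec_prune(su)
  internal <- (length(tr$tip.label) + 1):(length(tr$tip.label) + tr$Nnode)
  expect_true(all(pr$L[internal, ] >= 0))
  expect_true(all(abs(apply(pr$L[internal, , drop = FALSE], 1, max) - 1)
                  < 1e-12))
})
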