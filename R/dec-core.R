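## Core machinery for the dispersal-extinction-cladogenesis (DEC) process:
## bitmask state space over geographic areas, the anagenetic generator
## (per-area gain at rate d x number of source areas, per-area loss at rate
## e), and the cladogenetic event table (vicariance, subset sympatry,
## sympatric range-copying, optional founder-event jumps). Shared by the
## forward simulator, the pruning likelihood, and stochastic mapping.

## Number of set bits in a mask.
popcount <- function(mask) {
  n <- integer(length(mask))
  m <- mask
  while (any(m > 0L)) {
    n <- n + (m %% 2L)
    m <- m %/% 2L
  }
  n
}

mask_areas <- function(mask, areas) areas[bitwAnd(mask, bitwShiftL(1L, seq_along(areas) - 1L)) > 0L]

areas_to_mask <- function(x, areas) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  idx <- match(x, areas)
  if (anyNA(idx)) stop("unknown area(s): ", paste(x[is.na(idx)], collapse = ","),
                       call. = FALSE)
  as.integer(sum(bitwShiftL(1L, unique(idx) - 1L)))
}

mask_to_string <- function(mask, areas) {
  vapply(mask, function(m) paste(mask_areas(m, areas), collapse = ""), "")
}

## State space: masks 0 (empty, absorbing, index 1) then all non-empty
## masks with <= max_range_size areas, in increasing mask order.
dec_states <- function(n_areas, max_range_size = n_areas) {
  masks <- 0:(2^n_areas - 1L)
  masks <- masks[popcount(masks) <= max_range_size]
  list(masks = as.integer(masks),
       index = stats::setNames(seq_along(masks), masks),
       sizes = popcount(as.integer(masks)))
}

state_of <- function(mask, states) {
  i <- states$index[as.character(mask)]
  if (anyNA(i)) stop("range exceeds the maximum range size", call. = FALSE)
  unname(i)
}

## Anagenetic generator over the state space. Gains: R -> R+{k} at rate
## d * sum_{j in R} m[j,k] (m defaults to all ones: rate d * |R|); losses:
## R -> R-{k} at rate e per occupied area. Empty range is absorbing.
dec_generator <- function(d, e, n_areas, states, dispersal_matrix = NULL) {
  ns <- length(states$masks)
  Q <- matrix(0, ns, ns)
  m <- dispersal_matrix
  if (is.null(m)) m <- matrix(1, n_areas, n_areas)
  bits <- bitwShiftL(1L, seq_len(n_areas) - 1L)
  for (i in seq_len(ns)) {
    mask <- states$masks[i]
    if (mask == 0L) next
    inR <- which(bitwAnd(mask, bits) > 0L)
    for (k in seq_len(n_areas)) {
      if (bitwAnd(mask, bits[k]) > 0L) {          # loss of area k
        j <- states$index[as.character(mask - bits[k])]
        Q[i, j] <- Q[i, j] + e
      } else {                                    # gain of area k
        to <- mask + bits[k]
        j <- states$index[as.character(to)]
        if (!is.na(j)) Q[i, j] <- Q[i, j] + d * sum(m[inR, k])
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

## Cladogenetic event table for ancestral state mask: ordered daughter pairs
## (left, right) with probabilities. Non-jump DEC events share total weight
## (1 - j) equally; jump events (one daughter = ancestral range, other a
## single area outside it) share weight j equally. With j = 0 the table is
## the classical DEC set: sympatric copying for single-area ranges,
## subset sympatry and single-area vicariance for widespread ranges.
clado_events <- function(mask, n_areas, states, j = 0) {
  bits <- bitwShiftL(1L, seq_len(n_areas) - 1L)
  inR <- which(bitwAnd(mask, bits) > 0L)
  outR <- which(bitwAnd(mask, bits) == 0L)
  L <- integer(0); R <- integer(0); type <- character(0)
  if (length(inR) == 1L) {
    L <- mask; R <- mask; type <- "sympatry"
  } else {
    for (k in inR) {
      L <- c(L, mask, bits[k]);  R <- c(R, bits[k], mask)
      type <- c(type, "subset", "subset")
      rest <- mask - bits[k]
      L <- c(L, bits[k]); R <- c(R, rest); type <- c(type, "vicariance")
      if (popcount(rest) > 1L) {   # reversed order distinct only if |rest|>1
        L <- c(L, rest); R <- c(R, bits[k]); type <- c(type, "vicariance")
      }
    }
  }
  n_nonjump <- length(L)
  w <- rep(1 / n_nonjump, n_nonjump)
  if (j > 0 && length(outR)) {
    jl <- integer(0); jr <- integer(0)
    for (k in outR) {
      jl <- c(jl, mask, bits[k]); jr <- c(jr, bits[k], mask)
    }
    w <- c(rep((1 - j) / n_nonjump, n_nonjump),
           rep(j / length(jl), length(jl)))
    L <- c(L, jl); R <- c(R, jr)
    type <- c(type, rep("jump", length(jl)))
  }
  list(left = L, right = R, type = type, prob = w)
}

## Transition probability matrices for a set of branch lengths, from the
## eigendecomposition of Q (one decomposition, cheap per branch); falls back
## to Matrix::expm when the eigensystem is ill-conditioned or defective.
transition_matrices <- function(Q, lengths) {
  lengths <- unique(lengths)
  out <- vector("list", length(lengths))
  names(out) <- sprintf("%.17g", lengths)
  eig <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- if (!is.null(eig))
    tryCatch(solve(eig$vectors), error = function(e) NULL) else NULL
  ## accept the eigensystem only if it reconstructs Q accurately
  use_eig <- !is.null(Vi) && {
    recon <- Re(eig$vectors %*% (eig$values * Vi))
    max(abs(recon - Q)) < 1e-9 * max(1, max(abs(Q)))
  }
  if (use_eig) {
    V <- eig$vectors; lam <- eig$values
    for (i in seq_along(lengths)) {
      P <- V %*% (exp(lam * lengths[i]) * Vi)
      P <- Re(P)
      P[P < 0] <- 0
      out[[i]] <- P
    }
  } else {
    for (i in seq_along(lengths)) {
      P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * lengths[i])))
      P[P < 0] <- 0
      out[[i]] <- P
    }
  }
  out
}

lookup_P <- function(Pmats, len) Pmats[[sprintf("%.17g", len)]]

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object",
                                     call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  if (sum(tree$edge.length) <= 0)
    stop("tree has zero total length", call. = FALSE)
  if (!ape::is.binary(tree)) stop("tree must be bifurcating", call. = FALSE)
  invisible(tree)
}
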