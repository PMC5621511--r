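#' Stack species ranges into a richness grid
#'
#' Per-cell species richness is the count of species occupying the cell
#' (range-map overlap); the valid mask marks cells with at least one record.
#'
#' @param ranges a `range_set` (or plain list of logical occupancy matrices
#'   sharing one shape).
#' @param cell_size cell size in degrees; defaults to the range set's.
#' @return An object of class `richness_grid`: `richness` (integer matrix),
#'   `valid` (logical matrix), `shape`, `cell_size`, `n_species`.
#' @export
stack_richness <- function(ranges, cell_size = NULL) {
  occ <- occupancy_list(ranges)
  if (is.null(cell_size))
    cell_size <- if (inherits(ranges, "range_set")) ranges$cell_size else 1
  shape <- dim(occ[[1]])
  rich <- matrix(0L, shape[1], shape[2])
  for (o in occ) rich <- rich + o
  structure(list(richness = rich, valid = rich > 0L, shape = shape,
                 cell_size = cell_size, n_species = length(occ)),
            class = "richness_grid")
}

occupancy_list <- function(ranges) {
  occ <- if (inherits(ranges, "range_set")) ranges$occupancy else ranges
  if (!length(occ)) stop("empty range set", call. = FALSE)
  shape <- dim(occ[[1]])
  ok <- vapply(occ, function(o) identical(dim(o), shape), TRUE)
  if (!all(ok))
    stop("all occupancy grids must share one shape", call. = FALSE)
  lapply(occ, function(o) {
    o <- o * 1L
    storage.mode(o) <- "integer"
    o
  })
}

#' @export
print.richness_grid <- function(x, ...) {
  cat("<richness_grid> ", x$shape[1], "x", x$shape[2], " cells of ",
      x$cell_size, " deg; ", sum(x$valid), " occupied cells; max richness ",
      max(x$richness), "\n", sep = "")
  invisible(x)
}

#' Build a species-by-sites presence-absence matrix
#'
#' Rows are species, columns are grid cells (sites); by default only cells
#' with at least one species record are kept, so no column is all-zero.
#' Column names encode the cell as `"r<row>c<col>"`.
#'
#' @param ranges a `range_set` or list of occupancy matrices.
#' @param drop_empty drop sites without records (default `TRUE`).
#' @return Integer 0/1 matrix with species row names and site column names;
#'   attribute `cells` holds the (row, col) index of each site.
#' @export
build_matrix <- function(ranges, drop_empty = TRUE) {
  occ <- occupancy_list(ranges)
  species <- if (inherits(ranges, "range_set")) ranges$species
             else sprintf("sp%03d", seq_along(occ))
  M <- t(vapply(occ, as.vector, numeric(length(occ[[1]]))))
  storage.mode(M) <- "integer"
  shape <- dim(occ[[1]])
  cells <- cbind(row = rep(seq_len(shape[1]), shape[2]),
                 col = rep(seq_len(shape[2]), each = shape[1]))
  keep <- if (drop_empty) colSums(M) > 0L else rep(TRUE, ncol(M))
  if (!any(keep)) stop("no occupied cells", call. = FALSE)
  M <- M[, keep, drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  rownames(M) <- species
  colnames(M) <- sprintf("r%dc%d", cells[, 1], cells[, 2])
  attr(M, "cells") <- cells
  M
}

#' Aggregate ranges or a richness grid to a coarser resolution
#'
#' Per-species occupancy is aggregated by any-presence within each coarse
#' cell, then richness is recomputed from the coarse occupancies — never by
#' summing fine-cell richness, which would double-count species.
#'
#' @param ranges a `range_set` or list of occupancy matrices at the base
#'   resolution.
#' @param factor integer aggregation factor (new cell size = factor x base
#'   cell size); the grid is padded at the south/east edges if its extent is
#'   not an exact multiple.
#' @return A `richness_grid` at the coarse resolution, with the coarse
#'   `range_set` attached as attribute `ranges`.
#' @export
regrid <- function(ranges, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("'factor' must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  occ <- occupancy_list(ranges)
  cell_size <- if (inherits(ranges, "range_set")) ranges$cell_size else 1
  if (factor == 1L) return(stack_richness(occ, cell_size))
  shape <- dim(occ[[1]])
  nr2 <- ceiling(shape[1] / factor); nc2 <- ceiling(shape[2] / factor)
  ridx <- (seq_len(shape[1]) - 1L) %/% factor + 1L
  cidx <- (seq_len(shape[2]) - 1L) %/% factor + 1L
  coarse <- lapply(occ, function(o) {
    ## any-presence aggregation, done in two axis passes
    byrow <- rowsum(o, ridx)                       # nr2 x nc
    bycell <- t(rowsum(t(byrow), cidx))            # nr2 x nc2
    bycell > 0
  })
  stopifnot(all(dim(coarse[[1]]) == c(nr2, nc2)))
  out <- stack_richness(coarse, cell_size * factor)
  attr(out, "ranges") <- coarse
  out
}

#' Cohen's kappa agreement between two richness maps
#'
#' Both maps are binned into `n_classes` equal-width richness classes over
#' their joint value range (on cells valid in both maps), and Cohen's kappa
#' is computed over the per-cell class labels. 1 means total agreement of
#' the two class maps; negative values mean less agreement than expected
#' from the class frequencies alone.
#'
#' @param a,b `richness_grid` objects (or plain numeric matrices) on a
#'   common grid.
#' @param n_classes number of equal-width richness classes (default 10).
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_compare <- function(a, b, n_classes = 10) {
  va <- grid_values(a); vb <- grid_values(b)
  if (!identical(dim(va$x), dim(vb$x)))
    stop("maps must be co-registered on a common grid", call. = FALSE)
  ok <- va$valid & vb$valid
  if (!any(ok)) stop("valid masks are disjoint", call. = FALSE)
  x <- va$x[ok]; y <- vb$x[ok]
  rng <- range(c(x, y))
  if (rng[1] == rng[2]) {          # both maps constant over the joint range
    return(if (all(x == y)) 1 else 0)
  }
  br <- seq(rng[1], rng[2], length.out = n_classes + 1)
  cx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  cy <- findInterval(y, br, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- table(factor(cx, levels = seq_len(n_classes)),
               factor(cy, levels = seq_len(n_classes)))
  p <- tab / sum(tab)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

grid_values <- function(g) {
  if (inherits(g, "richness_grid")) list(x = g$richness, valid = g$valid)
  else if (is.matrix(g)) list(x = g, valid = !is.na(g))
  else stop("expected a richness_grid or a matrix", call. = FALSE)
}
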