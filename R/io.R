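#' Read and write labeled presence-absence matrices as CSV
#'
#' Comma-separated, UTF-8, "." decimal, header row with site labels and a
#' first column of species labels; round-trips exactly for integer data.
#'
#' @param M labeled matrix.
#' @param path file path.
#' @return `write_matrix` returns the path invisibly; `read_matrix` the
#'   matrix.
#' @export
write_matrix <- function(M, path) {
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text `.asc` grids (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header then row-major values, northernmost row first).
#' `NA` cells are written as the NODATA value.
#'
#' @param x numeric matrix or `richness_grid` (invalid cells become NODATA).
#' @param path file path.
#' @param xll,yll lower-left corner coordinates.
#' @param cell_size cell size in degrees.
#' @param nodata NODATA sentinel (default -9999).
#' @return `write_grid` returns the path invisibly; `read_grid` a list with
#'   `values` (matrix, `NA` for NODATA), `cell_size`, `xll`, `yll`.
#' @export
write_grid <- function(x, path, xll = 0, yll = 0, cell_size = NULL,
                       nodata = -9999) {
  if (inherits(x, "richness_grid")) {
    if (is.null(cell_size)) cell_size <- x$cell_size
    m <- x$richness
    m[!x$valid] <- NA
    x <- m
  }
  if (is.null(cell_size)) cell_size <- 1
  stopifnot(is.matrix(x))
  header <- c(paste("ncols", ncol(x)), paste("nrows", nrow(x)),
              paste("xllcorner", xll), paste("yllcorner", yll),
              paste("cellsize", cell_size), paste("NODATA_value", nodata))
  body <- apply(x, 1, function(row) {
    row[is.na(row)] <- nodata
    paste(format(row, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed ASCII grid: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!identical(keys, need))
    stop("malformed ASCII grid header in ", path, " (line ",
         which(keys != need)[1], ")", call. = FALSE)
  nc <- vals[1]; nr <- vals[2]
  rows <- lapply(seq_len(nr), function(i) {
    v <- as.numeric(strsplit(trimws(lines[6 + i]), "\\s+")[[1]])
    if (length(v) != nc)
      stop("malformed ASCII grid row ", i, " in ", path, call. = FALSE)
    v
  })
  m <- do.call(rbind, rows)
  m[m == vals[6]] <- NA
  list(values = m, cell_size = vals[5], xll = vals[3], yll = vals[4])
}

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()] that assigns synthetic labels to
#' unnamed internal nodes so the tree re-serializes stably.
#'
#' @param path newick file.
#' @return A `phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path,
                          call. = FALSE)
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree$node.label <- sprintf("nd%d", seq_len(tree$Nnode))
  tree
}

#' Read a tip-to-range coding table
#'
#' Two-column CSV (`tip`, `range`) with range strings such as `"B"` or
#' `"BC"`. The area set is taken from `areas`, or inferred (sorted unique
#' letters) when omitted. When a tree is supplied the coding is
#' cross-validated against its tip labels.
#'
#' @param path CSV path.
#' @param areas optional ordered area letters.
#' @param tree optional `phylo` to validate against.
#' @return A `range_coding`.
#' @export
read_coding <- function(path, areas = NULL, tree = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2) stop("coding file needs two columns (tip, range): ",
                         path, call. = FALSE)
  if (is.null(areas))
    areas <- sort(unique(unlist(strsplit(df[[2]], ""))))
  coding <- range_coding(df[[1]], df[[2]], areas)
  if (!is.null(tree)) {
    extra <- setdiff(names(coding$ranges), tree$tip.label)
    if (length(extra))
      stop("coding references tips absent from the tree: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  coding
}
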