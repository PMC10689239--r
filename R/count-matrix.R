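# The central container: a genes x cells UMI matrix with per-cell metadata.
# Kept deliberately light (a classed list around a Matrix sparse matrix) so
# every operation has an explicit, testable surface.

#' Create a count matrix with cell metadata
#'
#' @param counts Nonnegative genes x cells matrix (dense or `Matrix` sparse)
#'   of raw UMI counts, with gene symbols as rownames and cell barcodes as
#'   colnames.
#' @param cell_meta `data.frame` with one row per cell (rownames = cell
#'   barcodes, or a `cell` column) carrying at least `animal`, `timepoint`
#'   and `batch`.
#' @param timepoints Allowed timepoint labels, in experimental order.
#' @return A `count_matrix` object with elements `counts` (raw, sparse),
#'   `cell_meta`, `timepoints` and `norm` (normalized expression, `NULL`
#'   until [normalize_cells()] is applied).
#' @export
count_matrix <- function(counts, cell_meta,
                         timepoints = c("HC", "2h", "8h", "24h", "recall")) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || (ncol(counts) > 0L &&
                                    is.null(colnames(counts))))
    stopf("counts must have gene rownames and cell colnames")
  if (ncol(counts) == 0L) colnames(counts) <- character()
  if (any(counts@x < 0)) stopf("counts must be nonnegative")
  if (!is.data.frame(cell_meta)) stopf("cell_meta must be a data.frame")
  if ("cell" %in% names(cell_meta)) rownames(cell_meta) <- cell_meta$cell
  missing_meta <- setdiff(colnames(counts), rownames(cell_meta))
  if (length(missing_meta) > 0L)
    stopf("cell_meta is missing %d cells (e.g. %s)", length(missing_meta),
          paste(utils::head(missing_meta, 3), collapse = ", "))
  cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
  needed <- c("animal", "timepoint", "batch")
  absent <- setdiff(needed, names(cell_meta))
  if (length(absent) > 0L)
    stopf("cell_meta lacks column(s): %s", paste(absent, collapse = ", "))
  bad_tp <- setdiff(unique(cell_meta$timepoint), timepoints)
  if (length(bad_tp) > 0L)
    stopf("unknown timepoint label(s): %s", paste(bad_tp, collapse = ", "))
  structure(list(counts = counts, cell_meta = cell_meta,
                 timepoints = timepoints, norm = NULL),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is_normalized(x)) "normalized" else "raw"))
  tp <- table(factor(x$cell_meta$timepoint, levels = x$timepoints))
  cat("  timepoints:", paste(sprintf("%s=%d", names(tp), tp), collapse = " "),
      "\n")
  invisible(x)
}

#' Test whether a count matrix carries normalized expression
#' @param m A `count_matrix`.
#' @return Logical scalar.
#' @export
is_normalized <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  !is.null(m$norm)
}

#' Genes of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of gene symbols.
#' @export
genes <- function(m) rownames(m$counts)

#' Cells of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of cell barcodes.
#' @export
cells <- function(m) colnames(m$counts)

#' Subset a count matrix by genes and/or cells
#'
#' Subsets raw counts, normalized expression (if present) and metadata
#' consistently.
#'
#' @param m A `count_matrix`.
#' @param genes,cells Character vectors (or indices); `NULL` keeps all.
#' @return A `count_matrix`.
#' @export
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(m$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(m$counts)) else cells
  out <- m
  out$counts <- m$counts[gi, ci, drop = FALSE]
  if (!is.null(m$norm)) out$norm <- m$norm[gi, ci, drop = FALSE]
  out$cell_meta <- m$cell_meta[colnames(out$counts), , drop = FALSE]
  out
}

#' Expression values of a count matrix
#'
#' @param m A `count_matrix`.
#' @param values `"norm"` (default; errors when not normalized) or `"raw"`.
#' @return Sparse genes x cells matrix.
#' @export
expr_values <- function(m, values = c("norm", "raw")) {
  stopifnot(inherits(m, "count_matrix"))
  values <- match.arg(values)
  if (values == "raw") return(m$counts)
  if (!is_normalized(m)) stopf("matrix is not normalized; run normalize_cells()")
  m$norm
}

#' Cluster-wise mean expression profiles
#'
#' @param m A normalized `count_matrix` (or raw with `values = "raw"`).
#' @param labels Cluster label per cell (named by cell or in cell order).
#' @param log2p1 If `TRUE`, take `log2(x + 1)` before averaging.
#' @param values Which expression values to average.
#' @return Dense genes x clusters matrix of means.
#' @export
cluster_profiles <- function(m, labels, log2p1 = FALSE,
                             values = c("norm", "raw")) {
  values <- match.arg(values)
  x <- expr_values(m, values)
  labels <- align_labels(labels, colnames(x))
  if (log2p1) x <- log2(x + 1)
  lev <- sort(unique(labels))
  ind <- Matrix::sparseMatrix(i = seq_along(labels),
                              j = match(labels, lev),
                              x = 1, dims = c(length(labels), length(lev)))
  sizes <- as.numeric(table(factor(labels, levels = lev)))
  means <- as.matrix(x %*% ind) %*% diag(1 / sizes, length(lev))
  dimnames(means) <- list(rownames(x), as.character(lev))
  means
}

#' Per-cluster fraction of positive cells
#'
#' Fraction of cells with raw count > 0, per gene and cluster.
#'
#' @inheritParams cluster_profiles
#' @return Dense genes x clusters matrix of fractions in \[0, 1\].
#' @export
fraction_positive <- function(m, labels) {
  x <- m$counts
  labels <- align_labels(labels, colnames(x))
  lev <- sort(unique(labels))
  pos <- x
  pos@x <- rep(1, length(pos@x))
  ind <- Matrix::sparseMatrix(i = seq_along(labels),
                              j = match(labels, lev),
                              x = 1, dims = c(length(labels), length(lev)))
  sizes <- as.numeric(table(factor(labels, levels = lev)))
  frac <- as.matrix(pos %*% ind) %*% diag(1 / sizes, length(lev))
  dimnames(frac) <- list(rownames(x), as.character(lev))
  frac
}

# Align a (possibly named) label vector to a cell ordering.
align_labels <- function(labels, cell_ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(cell_ids, names(labels))
    if (length(miss) > 0L)
      stopf("labels missing for %d cells (e.g. %s)", length(miss),
            paste(utils::head(miss, 3), collapse = ", "))
    labels <- labels[cell_ids]
  } else if (length(labels) != length(cell_ids)) {
    stopf("labels length (%d) does not match number of cells (%d)",
          length(labels), length(cell_ids))
  }
  as.character(labels)
}
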