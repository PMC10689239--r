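# Cell quality filtering and normalization (first pass of the iterative
# clustering scheme).

#' Filter cells by UMI and detected-gene thresholds
#'
#' Retains cells with total UMI >= `min_umi` and detected genes (raw count
#' > 0) >= `min_genes`; thresholds are inclusive. The defaults are the
#' neuronal stream's; the non-neuronal stream uses the lower
#' (2000 UMI, 1000 genes) pair.
#'
#' @param m A raw (unnormalized) [count_matrix()].
#' @param min_umi Minimum total UMI per cell.
#' @param min_genes Minimum number of detected genes per cell.
#' @return Character vector of retained cell barcodes, in input order.
#' @export
filter_cells <- function(m, min_umi = 3000, min_genes = 2500) {
  stopifnot(inherits(m, "count_matrix"))
  if (is_normalized(m))
    stopf("filter_cells expects raw counts, not a normalized matrix")
  totals <- Matrix::colSums(m$counts)
  detected <- Matrix::colSums(m$counts > 0)
  cells(m)[totals >= min_umi & detected >= min_genes]
}

#' Normalize each cell to unit length times a fixed scale
#'
#' Every cell vector is normalized to length 1 — L1 (sum) by default, L2
#' optionally — and multiplied by `scale` (default 20,000). Under L1 this is
#' library-size normalization: each cell's entries sum to `scale`.
#'
#' @param m A raw [count_matrix()].
#' @param scale Scale factor applied after unit normalization.
#' @param norm `"l1"` (default) or `"l2"`.
#' @return The matrix with its `norm` slot filled (see [expr_values()]).
#' @export
normalize_cells <- function(m, scale = NORMALIZATION_SCALE,
                            norm = c("l1", "l2")) {
  stopifnot(inherits(m, "count_matrix"))
  norm <- match.arg(norm)
  lens <- switch(norm,
                 l1 = Matrix::colSums(m$counts),
                 l2 = sqrt(Matrix::colSums(m$counts^2)))
  zero <- which(lens == 0)
  if (length(zero) > 0L)
    stopf("cannot normalize zero-total cell(s): %s",
          paste(utils::head(cells(m)[zero], 5), collapse = ", "))
  m$norm <- m$counts %*% Matrix::Diagonal(ncol(m$counts), scale / lens)
  colnames(m$norm) <- colnames(m$counts)
  m
}

#' Exclude cells expressing any of a set of genes
#'
#' Used for the non-neuronal stream: cells with any raw count of the listed
#' genes (for example Gad2, Slc17a7, Slc17a6) are dropped.
#'
#' @param m A [count_matrix()] (raw or normalized; the raw counts decide).
#' @param genes Gene symbols; every one must exist in the matrix.
#' @return Character vector of retained cell barcodes, in input order.
#' @export
exclude_expressing <- function(m, genes) {
  stopifnot(inherits(m, "count_matrix"))
  unknown <- setdiff(genes, rownames(m$counts))
  if (length(unknown) > 0L)
    stopf("unknown gene symbol(s): %s", paste(unknown, collapse = ", "))
  if (length(genes) == 0L) return(cells(m))
  hits <- Matrix::colSums(m$counts[genes, , drop = FALSE] > 0)
  cells(m)[hits == 0]
}
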