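# Reading and writing count matrices (MatrixMarket + TSV sidecars, or dense
# TSV) and spatial targets.

#' Read a count matrix from disk
#'
#' Accepts either a directory holding `matrix.mtx` (genes x cells),
#' `genes.tsv`, `barcodes.tsv` and `cell_metadata.tsv` (columns `cell`,
#' `animal`, `timepoint`, `batch`), or a dense TSV file (first column gene
#' symbols, remaining columns cells) accompanied by
#' `<file>_metadata.tsv`. Duplicate gene symbols are disambiguated with
#' `.1`, `.2`, ... suffixes and a warning.
#'
#' @param path Directory or dense TSV file.
#' @param timepoints Allowed timepoint labels.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path,
                        timepoints = c("HC", "2h", "8h", "24h", "recall")) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stopf("no matrix.mtx under %s", path)
    header <- readLines(mtx, n = 1L)
    if (!startsWith(header, "%%MatrixMarket"))
      stopf("malformed MatrixMarket header at line 1 of %s", mtx)
    counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    gene_ids <- utils::read.table(file.path(path, "genes.tsv"),
                                  sep = "\t", stringsAsFactors = FALSE)[, 1]
    barcodes <- utils::read.table(file.path(path, "barcodes.tsv"),
                                  sep = "\t", stringsAsFactors = FALSE)[, 1]
    meta <- utils::read.table(file.path(path, "cell_metadata.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  } else {
    dense <- utils::read.table(path, sep = "\t", header = TRUE,
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
    gene_ids <- dense[, 1]
    counts <- as.matrix(dense[, -1, drop = FALSE])
    barcodes <- colnames(counts)
    meta_path <- sub("\\.tsv$", "_metadata.tsv", path)
    if (!file.exists(meta_path)) stopf("metadata file %s not found", meta_path)
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  }
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(barcodes))
    stopf("matrix dimensions (%d x %d) disagree with %d genes / %d barcodes",
          nrow(counts), ncol(counts), length(gene_ids), length(barcodes))
  if (anyDuplicated(gene_ids)) {
    warnf("%d duplicate gene symbol(s) disambiguated with suffixes",
          sum(duplicated(gene_ids)))
    gene_ids <- make.unique(gene_ids)
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  mismatch <- c(setdiff(barcodes, meta$cell), setdiff(meta$cell, barcodes))
  if (length(mismatch) > 0L)
    stopf("metadata/barcode mismatch for: %s",
          paste(utils::head(mismatch, 5), collapse = ", "))
  count_matrix(counts, meta, timepoints = timepoints)
}

#' Write a count matrix to disk
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#' `cell_metadata.tsv` under `path` (raw counts; normalization is not
#' persisted).
#'
#' @param m A [count_matrix()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(gene = genes(m)),
                     file.path(path, "genes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(cell = cells(m)),
                     file.path(path, "barcodes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- cbind(cell = cells(m), m$cell_meta)
  utils::write.table(meta, file.path(path, "cell_metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spatial target to disk
#'
#' Spots/voxels are written as `matrix.mtx` + `genes.tsv` + a positions CSV
#' (`unit, x, y[, z], region`).
#'
#' @param target A `spatial_target`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_spatial <- function(target, path) {
  stopifnot(inherits(target, "spatial_target"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(target$expr, sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(gene = rownames(target$expr)),
                     file.path(path, "genes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  pos <- cbind(target$coords, region = target$regions)
  utils::write.csv(pos, file.path(path, "positions.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
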