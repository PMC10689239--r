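# In-silico trapping differential expression: IEG-high versus IEG-low cells
# within a cell type, and general two-group DE with the same d statistic.

# mean log2(x + 1) normalized expression per gene over a cell set
mean_log_expr <- function(m, cell_idx) {
  x <- expr_values(m, "norm")[, cell_idx, drop = FALSE]
  Matrix::rowMeans(log2(x + 1))
}

#' Differential expression of activated (IEG-high) cells
#'
#' Splits the given cells (all conditioned-timepoint cells of one cell type)
#' into IEG-high and IEG-low by the any-gene activation flag (q = 95
#' convention) and registers, per gene, the difference
#' `d = mean_high - mean_low` of log2(x + 1) normalized expression. The top
#' lists keep genes with mean raw UMI > 1 over the analyzed cells and report
#' at most `top_n` genes by descending (up) or ascending (down) `d`.
#'
#' @param m A normalized [count_matrix()].
#' @param any_flags Named logical activation flags ([flag_active()]'s `any`).
#' @param cluster_cells Barcodes of the analyzed cells (conditioned
#'   timepoints of one cluster).
#' @param min_side Minimum cells required on each side.
#' @param top_n Cap on the reported top lists.
#' @return A `trap_de_result`: list with `table` (`data.frame` gene,
#'   mean_high, mean_low, d, mean_umi), `top_up`, `top_down`, `n_high`,
#'   `n_low`.
#' @export
trap_de <- function(m, any_flags, cluster_cells, min_side = 5, top_n = 100) {
  cluster_cells <- intersect(cluster_cells, cells(m))
  fl <- any_flags[cluster_cells]
  if (anyNA(fl)) stopf("activation flags missing for some cells")
  high <- cluster_cells[fl]
  low <- cluster_cells[!fl]
  if (length(high) < min_side || length(low) < min_side)
    stopf("need at least %d cells per side (IEG-high %d, IEG-low %d)",
          min_side, length(high), length(low))
  mh <- mean_log_expr(m, high)
  ml <- mean_log_expr(m, low)
  umi <- Matrix::rowMeans(m$counts[, cluster_cells, drop = FALSE])
  tab <- data.frame(gene = genes(m), mean_high = mh, mean_low = ml,
                    d = mh - ml, mean_umi = umi,
                    stringsAsFactors = FALSE, row.names = NULL)
  expressed <- tab[tab$mean_umi > 1, , drop = FALSE]
  top_up <- utils::head(expressed[order(-expressed$d), ], top_n)
  top_down <- utils::head(expressed[order(expressed$d), ], top_n)
  structure(list(table = tab, top_up = top_up, top_down = top_down,
                 n_high = length(high), n_low = length(low)),
            class = "trap_de_result")
}

#' @export
print.trap_de_result <- function(x, ...) {
  cat(sprintf("trap_de_result: %d high vs %d low cells; top up-regulated:\n",
              x$n_high, x$n_low))
  print(utils::head(x$top_up[, c("gene", "d", "mean_umi")], 5))
  invisible(x)
}

#' Rank genes by cluster frequency of differential expression
#'
#' Counts, per gene, the clusters of a class in which `d` exceeds
#' `d_threshold`, and ranks genes by that frequency (descending; ties
#' alphabetical).
#'
#' @param results Named list of `trap_de_result` objects (one per cluster).
#' @param d_threshold Difference above which a gene counts as differentially
#'   expressed in a cluster.
#' @return `data.frame` with `gene`, `frequency`, `rank`.
#' @export
de_frequency <- function(results, d_threshold = 0.5) {
  if (length(results) == 0L) stopf("need at least one cluster result")
  gene_ids <- results[[1]]$table$gene
  counts <- rowSums(vapply(results, function(r) {
    d <- r$table$d[match(gene_ids, r$table$gene)]
    !is.na(d) & d > d_threshold
  }, logical(length(gene_ids))))
  ord <- order(-counts, gene_ids)
  data.frame(gene = gene_ids[ord], frequency = as.integer(counts[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression between two arbitrary cell groups
#'
#' The same `d` statistic as [trap_de()] (difference of mean log2(x + 1)
#' normalized expression) between any two disjoint cell groups, for example
#' same-batch recall versus 2 h cells.
#'
#' @param m A normalized [count_matrix()].
#' @param cells_a,cells_b Disjoint, nonempty barcode sets.
#' @return `data.frame` with `gene`, `mean_a`, `mean_b`, `d`, `mean_umi`.
#' @export
group_de <- function(m, cells_a, cells_b) {
  if (length(cells_a) == 0L || length(cells_b) == 0L)
    stopf("both groups must be nonempty")
  overlap <- intersect(cells_a, cells_b)
  if (length(overlap) > 0L)
    stopf("groups overlap in %d cell(s) (e.g. %s)", length(overlap),
          overlap[[1]])
  ma <- mean_log_expr(m, cells_a)
  mb <- mean_log_expr(m, cells_b)
  umi <- Matrix::rowMeans(m$counts[, c(cells_a, cells_b), drop = FALSE])
  data.frame(gene = genes(m), mean_a = ma, mean_b = mb, d = ma - mb,
             mean_umi = umi, stringsAsFactors = FALSE, row.names = NULL)
}
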