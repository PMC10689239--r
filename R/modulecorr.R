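# Gene-module coexpression scoring: pairwise Pearson correlation within a
# (cell type, timepoint) group, aggregation to one p-value through the mean
# Fisher z, and the per-cluster score contrasting conditioning against the
# home-cage controls.

#' Eligibility of genes and clusters for module correlation
#'
#' Genes must be expressed (raw count > 0) in more than `min_gene_cells`
#' cells of the analyzed class; clusters must have at least
#' `min_cluster_per_tp` cells at every timepoint.
#'
#' @param m A [count_matrix()] restricted to one class.
#' @param clusters Cluster label per cell.
#' @param min_gene_cells Strict lower bound on expressing cells per gene.
#' @param min_cluster_per_tp Minimum cells per cluster and timepoint.
#' @return List with `genes` and `clusters` (character vectors).
#' @export
eligibility <- function(m, clusters, min_gene_cells = 200,
                        min_cluster_per_tp = 20) {
  clusters <- align_labels(clusters, cells(m))
  expressing <- Matrix::rowSums(m$counts > 0)
  ok_genes <- genes(m)[expressing > min_gene_cells]
  tp <- m$cell_meta$timepoint
  tp_lev <- intersect(m$timepoints, unique(tp))  # sampled timepoints
  lev <- sort(unique(clusters))
  ok_clusters <- lev[vapply(lev, function(cl) {
    sizes <- table(factor(tp[clusters == cl], levels = tp_lev))
    all(sizes >= min_cluster_per_tp)
  }, TRUE)]
  list(genes = ok_genes, clusters = ok_clusters)
}

#' Pairwise Pearson correlation of a gene list over a cell group
#'
#' @param m A normalized [count_matrix()].
#' @param genes Gene symbols (>= 2 usable after dropping zero-variance
#'   genes, which are removed with a warning).
#' @param cells Cell barcodes (>= 3).
#' @return List with `r` (symmetric correlation matrix, unit diagonal) and
#'   `n` (number of cells).
#' @export
pairwise_correlation <- function(m, genes, cells) {
  x <- expr_values(m, "norm")
  missing <- setdiff(genes, rownames(x))
  if (length(missing) > 0L)
    stopf("gene(s) absent: %s", paste(utils::head(missing, 3), collapse = ", "))
  if (length(cells) < 3L) stopf("need at least 3 cells")
  xm <- t(as.matrix(x[genes, cells, drop = FALSE]))
  sds <- apply(xm, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d zero-variance gene(s): %s", sum(sds == 0),
          paste(utils::head(genes[sds == 0], 3), collapse = ", "))
    xm <- xm[, sds > 0, drop = FALSE]
  }
  if (ncol(xm) < 2L) stopf("fewer than 2 usable genes")
  r <- stats::cor(xm)
  list(r = r, n = nrow(xm))
}

# log of the two-sided p for a Pearson r at n cells (t transform), computed
# in log space so extreme correlations do not underflow
correlation_log_p <- function(r, n) {
  if (n < 4L) stopf("need n >= 4 cells")
  r <- pmin(pmax(r, -1), 1)
  if (abs(r) >= 1) return(log(.Machine$double.xmin))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  log(2) + stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE,
                     log.p = TRUE)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Student-t transform `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom, evaluated in log space; `r = 0` gives exactly 1 and
#' `|r| = 1` is capped at the double-precision floor.
#'
#' @param r Correlation coefficient in \[-1, 1\].
#' @param n Number of cells (>= 4).
#' @return Two-sided p-value in (0, 1\].
#' @export
correlation_p <- function(r, n) {
  exp(correlation_log_p(r, n))
}

#' Aggregate a correlation matrix to a module score
#'
#' The off-diagonal upper-triangle correlations are averaged on the Fisher-z
#' scale, transformed back to a single `rbar`, converted to a two-sided p at
#' the group's cell count, and reported as `score = -log10(p)` capped at
#' 320.
#'
#' @param r Symmetric correlation matrix from [pairwise_correlation()].
#' @param n Number of cells.
#' @param cap Score cap (double-precision log floor).
#' @return List with `rbar`, `p`, `score`.
#' @export
module_score <- function(r, n, cap = 320) {
  ut <- r[upper.tri(r)]
  if (length(ut) == 0L) stopf("correlation matrix has no off-diagonal entries")
  z <- atanh(pmin(pmax(ut, -1 + 1e-15), 1 - 1e-15))
  rbar <- tanh(mean(z))
  log_p <- correlation_log_p(rbar, n)
  score <- min(-log_p / log(10), cap)
  list(rbar = rbar, p = exp(log_p), score = score)
}

#' Per-cluster correlation score
#'
#' The difference between the maximum module score among conditioned groups
#' (2 h, 8 h, 24 h, recall) and the maximum among home-cage controls
#' (batch A or B); may be negative.
#'
#' @param cfc_scores Scores of the conditioned (cluster, timepoint) groups.
#' @param hc_scores Scores of the home-cage groups (one per batch).
#' @return A single number, or `NA` when either side is empty/all-`NA`.
#' @export
cluster_score <- function(cfc_scores, hc_scores) {
  cfc_scores <- cfc_scores[!is.na(cfc_scores)]
  hc_scores <- hc_scores[!is.na(hc_scores)]
  if (length(cfc_scores) == 0L || length(hc_scores) == 0L) return(NA_real_)
  max(cfc_scores) - max(hc_scores)
}

#' Module correlation scores across clusters and timepoints
#'
#' Convenience wrapper running [pairwise_correlation()] and [module_score()]
#' for every eligible (cluster, timepoint) group and one gene module, then
#' [cluster_score()] per cluster. Home-cage groups are split by batch.
#'
#' @param m A normalized [count_matrix()] restricted to one class.
#' @param clusters Cluster label per cell.
#' @param module_genes Gene symbols of the module (intersected with the
#'   eligible gene set).
#' @param elig Optional precomputed [eligibility()] result.
#' @param hc_key Home-cage timepoint label.
#' @return List with `groups` (`data.frame` cluster, group, n, rbar, score)
#'   and `clusters` (`data.frame` cluster, cluster_score).
#' @export
module_score_table <- function(m, clusters, module_genes, elig = NULL,
                               hc_key = "HC") {
  clusters <- align_labels(clusters, cells(m))
  if (is.null(elig)) elig <- eligibility(m, clusters)
  genes_use <- intersect(module_genes, elig$genes)
  if (length(genes_use) < 2L)
    stopf("fewer than 2 eligible module genes")
  tp <- m$cell_meta$timepoint
  batch <- m$cell_meta$batch
  group_of <- ifelse(tp == hc_key, paste0(hc_key, "_", batch), tp)
  rows <- list()
  for (cl in elig$clusters) {
    for (g in unique(group_of)) {
      idx <- which(clusters == cl & group_of == g)
      if (length(idx) < 4L) next
      pc <- tryCatch(
        suppressWarnings(pairwise_correlation(m, genes_use, cells(m)[idx])),
        error = function(e) NULL)
      if (is.null(pc)) next
      ms <- module_score(pc$r, pc$n)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, group = g, n = pc$n, rbar = ms$rbar,
                   score = ms$score, stringsAsFactors = FALSE)
    }
  }
  groups <- do.call(rbind, rows)
  if (is.null(groups)) stopf("no scorable (cluster, timepoint) groups")
  cl_rows <- lapply(unique(groups$cluster), function(cl) {
    gr <- groups[groups$cluster == cl, ]
    is_hc <- startsWith(gr$group, paste0(hc_key, "_")) | gr$group == hc_key
    data.frame(cluster = cl,
               cluster_score = cluster_score(gr$score[!is_hc],
                                             gr$score[is_hc]),
               stringsAsFactors = FALSE)
  })
  list(groups = groups, clusters = do.call(rbind, cl_rows))
}

#' Transcriptome-wide correlation screen for one gene
#'
#' Within every eligible (cluster, conditioned-timepoint) group, genes
#' expressed in more than `min_cells_gene` cells are correlated with the
#' target gene; genes with two-sided p below `alpha` count as correlated.
#' Genes are ranked by the number of groups in which they are significant,
#' and the top `top_n` are returned for downstream enrichment.
#'
#' @param target Target gene symbol (excluded from its own ranking).
#' @param m A normalized [count_matrix()] restricted to one class.
#' @param clusters Cluster label per cell.
#' @param elig Optional precomputed [eligibility()] result (for clusters).
#' @param min_cells_gene Strict lower bound on expressing cells per gene
#'   within a group.
#' @param alpha Significance level.
#' @param hc_key Home-cage label (its groups are not screened).
#' @param top_n Length of the emitted top list.
#' @return List with `ranking` (`data.frame` gene, frequency, rank),
#'   `top` (character vector) and `n_groups` screened.
#' @export
gene_correlation_screen <- function(target, m, clusters, elig = NULL,
                                    min_cells_gene = 5, alpha = 0.01,
                                    hc_key = "HC", top_n = 200) {
  clusters <- align_labels(clusters, cells(m))
  if (!target %in% genes(m)) stopf("target gene '%s' absent", target)
  if (is.null(elig)) elig <- eligibility(m, clusters)
  x <- expr_values(m, "norm")
  tp <- m$cell_meta$timepoint
  counts_pos <- m$counts > 0
  freq <- stats::setNames(integer(nrow(x)), genes(m))
  n_groups <- 0L
  for (cl in elig$clusters) {
    for (t in setdiff(unique(tp), hc_key)) {
      idx <- which(clusters == cl & tp == t)
      if (length(idx) < 4L) next
      tv <- as.numeric(x[target, idx])
      if (stats::sd(tv) == 0) next  # target uninformative in this group
      n_groups <- n_groups + 1L
      ok <- Matrix::rowSums(counts_pos[, idx, drop = FALSE]) > min_cells_gene
      ok[target] <- FALSE
      if (!any(ok)) next
      xm <- as.matrix(x[ok, idx, drop = FALSE])
      sds <- apply(xm, 1L, stats::sd)
      xm <- xm[sds > 0, , drop = FALSE]
      if (nrow(xm) == 0L) next
      rv <- as.numeric(stats::cor(t(xm), tv))
      pv <- vapply(rv, correlation_p, 1, n = length(idx))
      sig <- rownames(xm)[pv < alpha]
      freq[sig] <- freq[sig] + 1L
    }
  }
  ord <- order(-freq, names(freq))
  ranking <- data.frame(gene = names(freq)[ord], frequency = freq[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE,
                        row.names = NULL)
  list(ranking = ranking,
       top = utils::head(ranking$gene[ranking$frequency > 0], top_n),
       n_groups = n_groups)
}
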