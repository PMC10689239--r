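# Percentile-based activation calling and the cluster IEG score.
#
# A cell is "activated" (IEG-high) when any panel gene exceeds its q-th
# percentile computed over all neurons pooled across timepoints. Per cluster,
# the fraction of activated cells per panel gene and timepoint forms an
# 8 x 5 matrix F; its column sums S give the per-timepoint activation load,
# and the IEG score is the maximum difference between post-conditioning
# timepoints and the home-cage control.

#' Percentile activation thresholds for the IEG panel
#'
#' The q-th percentile (linear interpolation, zeros included) of each panel
#' gene's normalized expression over all cells of `m` (all neurons, all
#' timepoints pooled).
#'
#' @param m A normalized [count_matrix()] restricted to neurons.
#' @param panel Panel gene symbols (default the packaged 8-IEG panel).
#' @param q Percentile in (0, 100); 90 for activation calling, 95 for
#'   in-silico trapping, 99 for enrichment counting.
#' @return An `activation_thresholds` list: `panel`, `q`, `theta` (named
#'   per-gene thresholds, normalized expression units).
#' @export
activation_thresholds <- function(m, panel = ieg_panel(), q = 90) {
  x <- expr_values(m, "norm")
  if (length(panel) == 0L) stopf("panel must be nonempty")
  missing <- setdiff(panel, rownames(x))
  if (length(missing) > 0L)
    stopf("panel gene(s) absent: %s", paste(missing, collapse = ", "))
  theta <- apply(as.matrix(x[panel, , drop = FALSE]), 1L,
                 stats::quantile, probs = q / 100, names = FALSE)
  structure(list(panel = panel, q = q,
                 theta = stats::setNames(theta, panel)),
            class = "activation_thresholds")
}

#' Flag activated cells
#'
#' A cell is flagged for a gene when its normalized expression exceeds that
#' gene's threshold (strict >). For genes whose threshold is 0 (zero in more
#' than q% of cells) any positive expression flags. The any-gene flag is the
#' union over the panel.
#'
#' @param m A normalized [count_matrix()] (same normalization as the
#'   thresholds).
#' @param thresholds An [activation_thresholds()].
#' @return List with `flags` (cells x panel logical matrix) and `any`
#'   (named logical vector).
#' @export
flag_active <- function(m, thresholds) {
  stopifnot(inherits(thresholds, "activation_thresholds"))
  x <- as.matrix(expr_values(m, "norm")[thresholds$panel, , drop = FALSE])
  cutoff <- ifelse(thresholds$theta > 0, thresholds$theta, 0)
  flags <- t(x > cutoff)
  dimnames(flags) <- list(colnames(x), thresholds$panel)
  list(flags = flags, any = apply(flags, 1L, any))
}

#' Per-cluster activation tables and IEG score
#'
#' For every cluster: `F` (panel genes x timepoints fraction of flagged
#' cells), `S[t] = sum_g F[g, t]`, and the IEG score
#' `max over post-conditioning timepoints of S[t] - S[HC]`. Clusters with
#' fewer than `min_cluster_cells` cells in total, or with any timepoint
#' below `min_group_cells`, are reported but marked low-confidence. With
#' `hc_mode = "batched"` the score is computed within each batch against
#' that batch's own home-cage cells and the maximum over batches is taken.
#'
#' @param flags The list returned by [flag_active()].
#' @param clusters Cluster label per cell.
#' @param timepoints Timepoint label per cell.
#' @param hc_key Label of the home-cage control group.
#' @param batches Batch label per cell (required for `hc_mode = "batched"`).
#' @param hc_mode `"pooled"` (default) or `"batched"`.
#' @param min_cluster_cells,min_group_cells Confidence-mask thresholds.
#' @return An `activation_tables` list: per-cluster `F`, `S`, `score`
#'   (`data.frame` with `cluster`, `score`, `n_cells`, `min_group`,
#'   `low_confidence`).
#' @export
activation_tables <- function(flags, clusters, timepoints, hc_key = "HC",
                              batches = NULL,
                              hc_mode = c("pooled", "batched"),
                              min_cluster_cells = 60, min_group_cells = 20) {
  hc_mode <- match.arg(hc_mode)
  fl <- flags$flags
  stopifnot(length(clusters) == nrow(fl), length(timepoints) == nrow(fl))
  if (hc_mode == "batched" && is.null(batches))
    stopf("hc_mode = 'batched' needs per-cell batch labels")
  tp_lev <- unique(timepoints)
  tp_lev <- c(intersect(hc_key, tp_lev), setdiff(tp_lev, hc_key))
  cfc <- setdiff(tp_lev, hc_key)
  lev <- sort(unique(as.character(clusters)))

  frac_tab <- function(idx, tps) {
    vapply(tps, function(tp) {
      rows <- idx[timepoints[idx] == tp]
      if (length(rows) == 0L) rep(NA_real_, ncol(fl))
      else colMeans(fl[rows, , drop = FALSE])
    }, numeric(ncol(fl)))
  }

  F_list <- list()
  S_list <- list()
  rows <- lapply(lev, function(cl) {
    idx <- which(clusters == cl)
    Fm <- frac_tab(idx, tp_lev)
    rownames(Fm) <- colnames(fl)
    S <- colSums(Fm)
    F_list[[cl]] <<- Fm
    S_list[[cl]] <<- S
    group_sizes <- table(factor(timepoints[idx], levels = tp_lev))
    score <- if (hc_mode == "pooled") {
      if (is.na(S[hc_key]) || all(is.na(S[cfc]))) NA_real_
      else max(S[cfc] - S[hc_key], na.rm = TRUE)
    } else {
      per_batch <- vapply(unique(batches[idx]), function(b) {
        bi <- idx[batches[idx] == b]
        Fb <- frac_tab(bi, tp_lev)
        Sb <- colSums(Fb)
        if (is.na(Sb[hc_key]) || all(is.na(Sb[cfc]))) NA_real_
        else max(Sb[cfc] - Sb[hc_key], na.rm = TRUE)
      }, 1)
      if (all(is.na(per_batch))) NA_real_ else max(per_batch, na.rm = TRUE)
    }
    data.frame(cluster = cl, score = score, n_cells = length(idx),
               min_group = min(group_sizes),
               low_confidence = length(idx) < min_cluster_cells ||
                 min(group_sizes) < min_group_cells,
               stringsAsFactors = FALSE)
  })
  structure(list(F = F_list, S = S_list, score = do.call(rbind, rows),
                 timepoints = tp_lev, hc_key = hc_key),
            class = "activation_tables")
}

#' @export
print.activation_tables <- function(x, ...) {
  cat(sprintf("activation_tables: %d clusters, timepoints %s\n",
              nrow(x$score), paste(x$timepoints, collapse = " ")))
  print(utils::head(x$score[order(-x$score$score), ], 10))
  invisible(x)
}

#' Observed versus expected activated fractions
#'
#' Per cluster and timepoint, the observed fraction of activated (any-flag)
#' cells against the fraction expected by chance — the global flagged
#' fraction at that timepoint — and their ratio (undefined where the
#' expectation is 0).
#'
#' @param any_flags Named logical vector (the `any` element of
#'   [flag_active()], typically at q = 99).
#' @param clusters,timepoints Labels per cell.
#' @return `data.frame` with `cluster`, `timepoint`, `n`, `observed`,
#'   `expected`, `ratio`.
#' @export
observed_vs_expected <- function(any_flags, clusters, timepoints) {
  stopifnot(length(any_flags) == length(clusters),
            length(any_flags) == length(timepoints))
  tp_lev <- unique(timepoints)
  global <- vapply(tp_lev, function(tp) mean(any_flags[timepoints == tp]), 1)
  out <- expand.grid(cluster = sort(unique(as.character(clusters))),
                     timepoint = tp_lev, stringsAsFactors = FALSE)
  out$n <- mapply(function(cl, tp)
    sum(clusters == cl & timepoints == tp), out$cluster, out$timepoint)
  out$observed <- mapply(function(cl, tp) {
    idx <- clusters == cl & timepoints == tp
    if (!any(idx)) NA_real_ else mean(any_flags[idx])
  }, out$cluster, out$timepoint)
  out$expected <- global[out$timepoint]
  out$ratio <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  out
}

#' Time-dynamic fold change of panel genes
#'
#' Per cluster and panel gene, the mean expression among threshold-exceeding
#' cells at each timepoint relative to the home-cage value, with a 0.1
#' pseudocount on both sides; missing where no cell qualifies.
#'
#' @param m A normalized [count_matrix()].
#' @param thresholds An [activation_thresholds()] (q = 90 convention).
#' @param clusters,timepoints Labels per cell.
#' @param hc_key Home-cage label.
#' @param eps Pseudocount.
#' @return `data.frame` with `cluster`, `gene`, `timepoint`, `n_qualifying`,
#'   `fold_change`.
#' @export
fold_change_dynamics <- function(m, thresholds, clusters, timepoints,
                                 hc_key = "HC", eps = 0.1) {
  x <- as.matrix(expr_values(m, "norm")[thresholds$panel, , drop = FALSE])
  cutoff <- ifelse(thresholds$theta > 0, thresholds$theta, 0)
  tp_lev <- unique(timepoints)
  lev <- sort(unique(as.character(clusters)))
  rows <- list()
  for (cl in lev) {
    for (g in thresholds$panel) {
      cond_mean <- vapply(tp_lev, function(tp) {
        idx <- clusters == cl & timepoints == tp
        v <- x[g, idx]
        v <- v[v > cutoff[[g]]]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, 1)
      n_qual <- vapply(tp_lev, function(tp) {
        idx <- clusters == cl & timepoints == tp
        sum(x[g, idx] > cutoff[[g]])
      }, 1)
      fc <- (cond_mean + eps) / (cond_mean[[hc_key]] + eps)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, gene = g, timepoint = tp_lev,
                   n_qualifying = n_qual, fold_change = fc,
                   stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
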