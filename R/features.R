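# Feature selection: CV-versus-mean ranking and the elbow criterion used
# throughout the pipeline (gene count, PC count, DBSCAN eps, perplexity).

# Chord-distance ("bending point closest to the origin", Kneedle-style)
# elbow of an arbitrary curve: index of maximum perpendicular distance to the
# chord joining the first and last points of the min-max normalized curve.
chord_elbow <- function(values) {
  n <- length(values)
  if (n < 3L) return(1L)
  rng <- range(values)
  if (diff(rng) == 0) return(1L)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (values - rng[1]) / diff(rng)
  # distance from (x, y) to the line through (0, y1) and (1, yn)
  dy <- y[n] - y[1]
  d <- abs(dy * x - (y - y[1])) / sqrt(dy^2 + 1)
  # ties (within fp noise, e.g. an exactly linear series) -> smallest index
  which(d >= max(d) - 1e-12)[1L]
}

#' Find the elbow of a decreasing series
#'
#' Returns the index of maximum perpendicular distance to the chord joining
#' the first and last points of the normalized curve; ties break to the
#' smallest index, and a constant (or too-short) series returns 1. Used to
#' pick the number of selected genes, the number of PCs, per-cell neighbor
#' counts and the DBSCAN radius.
#'
#' @param values Nonincreasing numeric series of length >= 3.
#' @return Integer index of the bend.
#' @export
#' @examples
#' find_elbow(c(10, 9, 1, 0.9, 0.8))
find_elbow <- function(values) {
  if (length(values) < 3L) return(1L)
  if (any(diff(values) > 1e-8 * max(abs(values), 1)))
    stopf("find_elbow expects a nonincreasing series")
  chord_elbow(values)
}

# Elbow of a decreasing curve via the chord rule applied to its cumulative
# form: the bend falls where the marginal value crosses the average
# increment. Robust to a few extreme leading values that would otherwise
# pull the plain chord elbow to the very top of the curve.
cumulative_elbow <- function(values) {
  chord_elbow(cumsum(values - min(values)))
}

#' Rank genes by variability and select features
#'
#' Eligible genes are expressed (raw count > 0) in at least `min_cells` cells
#' but in fewer than `max_cell_frac` of all cells. Eligible genes are ranked
#' by the vertical residual of log2(CV) above a least-squares quadratic on
#' log2(mean) (both on normalized expression); the number selected is the
#' bending point of the sorted residual curve, located by the chord
#' criterion on the cumulative curve so that a few extreme residuals (such
#' as the class markers) do not truncate the selection. Genes on the
#' exclusion list
#' (immediate-early, sex and context-irrelevant marker genes) are never
#' selected.
#'
#' @param m A normalized [count_matrix()].
#' @param min_cells Minimum number of expressing cells.
#' @param max_cell_frac Maximum fraction of expressing cells (exclusive).
#' @param excluded Gene symbols barred from selection; defaults to the
#'   packaged IEG + sex-gene lists.
#' @return A `data.frame` (gene, mean, cv, residual, rank, selected) ordered
#'   by rank, with the selected genes first.
#' @export
rank_features <- function(m, min_cells = 5, max_cell_frac = 0.5,
                          excluded = c(ieg_exclusion_genes(), sex_genes())) {
  x <- expr_values(m, "norm")
  n_cells <- ncol(x)
  expressing <- Matrix::rowSums(m$counts > 0)
  eligible <- expressing >= min_cells & expressing < max_cell_frac * n_cells
  eligible <- eligible & !(rownames(x) %in% excluded)
  if (sum(eligible) < 10L)
    stopf("only %d eligible genes; need at least 10", sum(eligible))

  xe <- x[eligible, , drop = FALSE]
  mu <- Matrix::rowMeans(xe)
  ex2 <- Matrix::rowMeans(xe^2)
  v <- pmax(ex2 - mu^2, 0) * n_cells / (n_cells - 1)
  cv <- sqrt(v) / mu

  # quadratic in log-log space: the CV-mean relation is curved at both the
  # sparse and the abundant end, and a straight line promotes ultra-sparse
  # genes whose CV it underestimates
  lm2 <- log2(mu)
  fit <- stats::lm.fit(cbind(1, lm2, lm2^2), log2(cv))
  residual <- fit$residuals

  ord <- order(residual, decreasing = TRUE)
  n_sel <- cumulative_elbow(residual[ord])
  out <- data.frame(gene = rownames(xe)[ord], mean = mu[ord], cv = cv[ord],
                    residual = residual[ord], rank = seq_along(ord),
                    selected = seq_along(ord) <= n_sel,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Genes selected by [rank_features()]
#' @param ranking The `data.frame` returned by [rank_features()].
#' @return Character vector of selected gene symbols.
#' @export
selected_features <- function(ranking) ranking$gene[ranking$selected]
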