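# Mapping cluster expression profiles onto spatial units (capture spots or
# atlas voxels) by Pearson correlation.

#' Features shared between the single-cell and spatial datasets
#'
#' Runs feature selection independently on the single-cell matrix and on the
#' spatial target (spots treated as "micro-bulk" cells), removes
#' non-neuronal marker genes first, and intersects the two selections.
#'
#' @param m A normalized single-cell [count_matrix()].
#' @param target A `spatial_target` in spot mode.
#' @param remove_genes Genes stripped before selection (default the
#'   non-neuronal markers).
#' @param min_intersection Error below this intersection size.
#' @param ... Passed to [rank_features()].
#' @return Character vector of shared feature genes.
#' @export
shared_features <- function(m, target, remove_genes = nonneuronal_markers(),
                            min_intersection = 20, ...) {
  stopifnot(inherits(target, "spatial_target"))
  sel_sc <- selected_features(rank_features(m, excluded = unique(
    c(ieg_exclusion_genes(), sex_genes(), remove_genes)), ...))
  tm <- count_matrix(target$expr,
                     data.frame(cell = colnames(target$expr),
                                animal = "spatial", timepoint = "HC",
                                batch = "A"))
  tm <- normalize_cells(tm)
  sel_sp <- selected_features(rank_features(tm, excluded = unique(
    c(ieg_exclusion_genes(), sex_genes(), remove_genes)), ...))
  shared <- intersect(sel_sc, sel_sp)
  if (length(shared) < min_intersection)
    stopf("only %d shared features (need >= %d)", length(shared),
          min_intersection)
  shared
}

#' Correlate cluster profiles with spatial units
#'
#' Pearson correlation of every cluster's mean expression profile with every
#' unit's expression over the shared features, both sides normalized to the
#' same scale per unit. Zero-variance units are marked undefined (`NA`), not
#' zero.
#'
#' @param cluster_means Genes x clusters matrix of mean normalized
#'   expression ([cluster_profiles()]).
#' @param target A `spatial_target`.
#' @param features Feature genes (>= 3) present in both.
#' @return A `spatial_correlation`: list with `rho` (clusters x units),
#'   `features`, `target_mode`, `regions`, `coords`.
#' @export
correlate_profiles <- function(cluster_means, target, features) {
  stopifnot(inherits(target, "spatial_target"))
  if (length(features) < 3L) stopf("need at least 3 features")
  missing <- setdiff(features, rownames(cluster_means))
  missing <- c(missing, setdiff(features, rownames(target$expr)))
  if (length(missing) > 0L)
    stopf("feature(s) absent: %s",
          paste(utils::head(unique(missing), 3), collapse = ", "))
  a <- cluster_means[features, , drop = FALSE]
  b <- target$expr[features, , drop = FALSE]
  # per-unit total normalization puts counts and energies on one scale
  tot <- colSums(b)
  b <- sweep(b, 2L, ifelse(tot > 0, tot, 1), `/`)
  sds <- apply(b, 2L, stats::sd)
  rho <- suppressWarnings(stats::cor(a, b))
  rho[, sds == 0] <- NA_real_
  structure(list(rho = rho, features = features, target_mode = target$mode,
                 regions = target$regions, coords = target$coords),
            class = "spatial_correlation")
}

#' @export
print.spatial_correlation <- function(x, ...) {
  cat(sprintf("spatial_correlation: %d clusters x %d units (%s), %d features\n",
              nrow(x$rho), ncol(x$rho), x$target_mode, length(x$features)))
  invisible(x)
}

#' Region-wise summary of spatial correlations
#'
#' Mean correlation of every cluster over the units of each region;
#' undefined units are skipped, and regions with no valid unit are missing.
#'
#' @param sc A `spatial_correlation`.
#' @return Clusters x regions matrix of mean rho.
#' @export
regionwise_summary <- function(sc) {
  stopifnot(inherits(sc, "spatial_correlation"))
  regions <- sort(unique(sc$regions))
  out <- vapply(regions, function(r) {
    cols <- sc$rho[, sc$regions == r, drop = FALSE]
    rowMeans(cols, na.rm = TRUE)
  }, numeric(nrow(sc$rho)))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(sc$rho), regions)
  out
}

#' Render a dominant or weighted spatial map
#'
#' Dominant mode labels each unit with its argmax-correlation cluster (ties
#' to the lower cluster index). Weighted mode blends per-cluster colors by
#' the positive part of rho, normalized per unit (a convex combination);
#' units with no positive correlation get the background color.
#'
#' @param sc A `spatial_correlation`.
#' @param mode `"dominant"` or `"weighted"`.
#' @param colors Named vector of hex colors per cluster (defaults to a
#'   rainbow palette).
#' @param background Color for undefined / all-nonpositive units.
#' @return `data.frame` with `unit`, coordinates, `region`, `label`
#'   (dominant cluster or `NA`) and `color`.
#' @export
render_map <- function(sc, mode = c("dominant", "weighted"), colors = NULL,
                       background = "#DDDDDD") {
  stopifnot(inherits(sc, "spatial_correlation"))
  mode <- match.arg(mode)
  cl <- rownames(sc$rho)
  if (is.null(colors))
    colors <- stats::setNames(grDevices::rainbow(length(cl)), cl)
  out <- sc$coords
  out$region <- sc$regions
  rho <- sc$rho
  lab <- rep(NA_character_, ncol(rho))
  col <- rep(background, ncol(rho))
  for (j in seq_len(ncol(rho))) {
    v <- rho[, j]
    if (all(is.na(v))) next
    if (mode == "dominant") {
      lab[j] <- cl[which.max(v)]  # ties -> lower cluster index
      col[j] <- colors[[lab[j]]]
    } else {
      w <- pmax(v, 0)
      w[is.na(w)] <- 0
      if (sum(w) <= 0) next
      w <- w / sum(w)
      rgb <- grDevices::col2rgb(colors[cl]) / 255
      mix <- as.numeric(rgb %*% w)
      lab[j] <- cl[which.max(v)]
      col[j] <- grDevices::rgb(mix[1], mix[2], mix[3])
    }
  }
  out$label <- lab
  out$color <- col
  out
}

#' Min-max normalize correlations per cluster
#'
#' Rescales every cluster's correlations across units to \[0, 1\] for global
#' pattern comparison in heatmap exports.
#'
#' @param sc A `spatial_correlation`.
#' @return Clusters x units matrix of rescaled rho.
#' @export
normalize_rho <- function(sc) {
  stopifnot(inherits(sc, "spatial_correlation"))
  t(apply(sc$rho, 1L, function(v) {
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  }))
}
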