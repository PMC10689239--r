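# Density-based cluster calling on the 2D embedding, kNN outlier
# reassignment, and within-cluster 1D ordering.

#' Cluster an embedding with DBSCAN
#'
#' Density-based clustering of the 2D t-SNE coordinates. When `eps` is
#' `NULL` it defaults to the elbow of the sorted k-distance curve
#' (k = `min_pts`). Cells DBSCAN labels as outliers (label 0) are excluded
#' from cluster membership; [reassign_outliers_knn()] can regroup them.
#'
#' @param coords Units x 2 coordinate matrix (finite).
#' @param eps Neighborhood radius; `NULL` for the k-distance elbow default.
#' @param min_pts Minimum neighborhood size (self included) of a core point.
#' @return A `cluster_set`: list with `labels` (named integer vector,
#'   0 = outlier, clusters numbered 1..K contiguously), `eps`, `min_pts`.
#' @export
cluster_embedding <- function(coords, eps = NULL, min_pts = 10) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stopf("coordinates must be finite")
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))

  if (is.null(eps)) {
    kdist <- vapply(seq_len(n), function(i)
      sort(d[i, -i], partial = min_pts)[min_pts], 1)
    curve <- sort(kdist, decreasing = TRUE)
    eps <- curve[chord_elbow(curve)]
  }

  nb <- apply(d <= eps, 1L, which, simplify = FALSE)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cid <- cid + 1L
    labels[i] <- cid
    queue <- i
    while (length(queue) > 0L) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      reach <- nb[[j]][labels[nb[[j]]] == 0L]
      labels[reach] <- cid
      queue <- c(queue, reach[core[reach]])
    }
  }
  if (cid == 0L)
    stopf(paste("all points are outliers; increase eps (current %.3g)",
                "or decrease min_pts"), eps)
  names(labels) <- rownames(coords)
  structure(list(labels = labels, eps = eps, min_pts = min_pts),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, %d outliers of %d points (eps %.3g)\n",
              max(x$labels), sum(x$labels == 0L), length(x$labels), x$eps))
  invisible(x)
}

#' Reassign outliers to their nearest cluster by kNN vote
#'
#' Each outlier (label 0 or `NA`) receives the modal label of its `k`
#' nearest non-outlier points; ties go to the single nearest neighbor's
#' label. Used to regroup DBSCAN outlier spots (and optionally cells).
#'
#' @param coords Units x d coordinate matrix.
#' @param labels Integer or character labels; 0/`NA` marks outliers.
#' @param k Number of neighbors voting.
#' @return Labels with every outlier reassigned.
#' @export
reassign_outliers_knn <- function(coords, labels, k = 10) {
  coords <- as.matrix(coords)
  out <- which(is.na(labels) | labels == 0)
  if (length(out) == 0L) return(labels)
  keep <- setdiff(seq_len(nrow(coords)), out)
  if (length(keep) == 0L) stopf("no non-outlier points to vote")
  kk <- min(k, length(keep))
  numeric_in <- is.numeric(labels)
  labels <- as.character(labels)
  for (i in out) {
    dv <- sqrt(colSums((t(coords[keep, , drop = FALSE]) - coords[i, ])^2))
    nn <- keep[order(dv)[seq_len(kk)]]
    votes <- table(labels[nn])
    winners <- names(votes)[votes == max(votes)]
    labels[i] <- if (length(winners) == 1L) winners else
      labels[keep[which.min(dv)]]
  }
  if (numeric_in) labels <- as.numeric(labels)
  labels
}

#' Order the cells of one cluster along a 1D embedding
#'
#' Sorts a cluster's cells by a one-dimensional t-SNE of their expression
#' (correlation distance on log2(x + 1) normalized values), initialized
#' from the first principal coordinate as in the 2D embedding. Clusters of
#' fewer than 3 cells keep their input order. Deterministic given `seed`.
#'
#' @param m A normalized [count_matrix()].
#' @param cluster_cells Barcodes of the cluster's cells.
#' @param seed Integer seed.
#' @return `cluster_cells` permuted into 1D order.
#' @export
order_within_cluster <- function(m, cluster_cells, seed = 0) {
  if (length(cluster_cells) < 3L) return(cluster_cells)
  x <- expr_values(m, "norm")[, cluster_cells, drop = FALSE]
  d <- correlation_dist(t(log2(as.matrix(x) + 1)))
  n <- length(cluster_cells)
  perp <- max(2, min(30, floor((n - 1) / 3)))
  if (n < 3 * perp + 1) perp <- max(2, floor((n - 1) / 3))
  pc1 <- stats::cmdscale(d, k = 1)[, 1]
  if (n < 7L) return(cluster_cells[order(pc1)])  # too small for t-SNE
  y0 <- matrix(pc1 / max(stats::sd(pc1), 1e-12) * 1e-4, ncol = 1)
  y <- with_seed(seed,
    Rtsne::Rtsne(d, dims = 1, is_distance = TRUE, perplexity = perp,
                 theta = 0.5, pca = FALSE, check_duplicates = FALSE,
                 Y_init = y0, max_iter = 500, verbose = FALSE))$Y[, 1]
  cluster_cells[order(y)]
}

#' Merge near-identical clusters
#'
#' Replaces the manual "merge clusters with extremely high similarity" step:
#' clusters whose mean log2(x + 1) expression profiles correlate above
#' `threshold` are merged (transitively), plus any explicit `merge_list`
#' pairs.
#'
#' @param m A normalized [count_matrix()].
#' @param labels Cluster label per cell.
#' @param threshold Pearson r above which two clusters merge.
#' @param merge_list Optional list of label pairs to force-merge.
#' @return Relabeled cluster vector (contiguous integers as characters).
#' @export
merge_similar_clusters <- function(m, labels, threshold = 0.995,
                                   merge_list = list()) {
  labels <- align_labels(labels, cells(m))
  means <- cluster_profiles(m, labels, log2p1 = TRUE)
  lev <- colnames(means)
  r <- stats::cor(means)
  parent <- seq_along(lev)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) parent[find(i)] <<- find(j)
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (i < j && r[i, j] > threshold) union2(i, j)
  }
  for (p in merge_list) {
    ij <- match(as.character(p), lev)
    if (anyNA(ij)) stopf("merge_list refers to unknown cluster(s)")
    union2(ij[1], ij[2])
  }
  roots <- vapply(seq_along(lev), find, 1L)
  new_ids <- match(roots, unique(roots))
  stats::setNames(as.character(new_ids[match(labels, lev)]), names(labels))
}
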