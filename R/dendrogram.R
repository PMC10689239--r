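# Cluster dendrogram: Ward linkage on the correlation distances of
# PCA-projected cluster means, optimal leaf ordering, and branch-point
# marker genes.

#' Build the cluster dendrogram
#'
#' Expression is log2(x + 1)-transformed, averaged per cluster, projected by
#' PCA, and the projections are linked by the Ward criterion on correlation
#' distance. Leaves are then permuted by optimal leaf ordering (minimum sum
#' of adjacent-leaf distances among all orders consistent with the tree).
#'
#' @param m A normalized [count_matrix()].
#' @param labels Cluster label per cell (>= 2 clusters).
#' @param max_pcs Upper bound on the number of PCs of the cluster means.
#' @return A `taxonomy_dendrogram`: list with `hclust`, `leaf_order`
#'   (cluster labels left to right) and `junctions` (per merge: `id`,
#'   `left`, `right` cluster sets).
#' @export
build_dendrogram <- function(m, labels, max_pcs = 20) {
  labels <- align_labels(labels, cells(m))
  means <- cluster_profiles(m, labels, log2p1 = TRUE)
  lev <- colnames(means)
  if (length(lev) < 2L) stopf("need at least 2 clusters for a dendrogram")
  k <- min(max_pcs, length(lev) - 1L, nrow(means))
  proj <- stats::prcomp(t(means), center = TRUE, rank. = k)$x
  d <- if (length(lev) == 2L) {
    matrix(c(0, 1, 1, 0), 2, dimnames = list(lev, lev))
  } else {
    correlation_dist(proj)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  ord <- optimal_leaf_order(hc, d)
  hc$order <- ord

  junctions <- lapply(seq_len(nrow(hc$merge)), function(i) {
    list(id = i,
         left = lev[merge_leaves(hc$merge, hc$merge[i, 1])],
         right = lev[merge_leaves(hc$merge, hc$merge[i, 2])])
  })
  structure(list(hclust = hc, leaf_order = lev[ord], junctions = junctions),
            class = "taxonomy_dendrogram")
}

#' @export
print.taxonomy_dendrogram <- function(x, ...) {
  cat(sprintf("taxonomy_dendrogram: %d clusters\n  leaf order: %s\n",
              length(x$leaf_order), paste(x$leaf_order, collapse = " ")))
  invisible(x)
}

# leaves under one entry of an hclust merge matrix
merge_leaves <- function(merge, node) {
  if (node < 0) return(-node)
  c(merge_leaves(merge, merge[node, 1]), merge_leaves(merge, merge[node, 2]))
}

# Optimal leaf ordering (Bar-Joseph dynamic program): among the 2^(n-1)
# orders obtainable by flipping internal nodes, find the one minimizing the
# sum of distances between adjacent leaves. Exact; intended for cluster-level
# trees (tens of leaves).
optimal_leaf_order <- function(hc, d) {
  merge <- hc$merge
  n <- nrow(merge) + 1L
  d <- as.matrix(d)

  solve_node <- function(node) {
    if (node < 0) {
      leaf <- -node
      return(list(leaves = leaf,
                  M = matrix(0, 1, 1, dimnames = list(leaf, leaf)),
                  split = NULL))
    }
    A <- solve_node(merge[node, 1])
    B <- solve_node(merge[node, 2])
    la <- A$leaves; lb <- B$leaves
    leaves <- c(la, lb)
    nl <- length(leaves)
    M <- matrix(Inf, nl, nl, dimnames = list(leaves, leaves))
    argm <- matrix(NA_integer_, nl, nl, dimnames = list(leaves, leaves))
    argk <- matrix(NA_integer_, nl, nl, dimnames = list(leaves, leaves))
    fill <- function(X, Y) {
      # ends u in X, w in Y; interior seam m in X adjacent to k in Y
      for (u in X$leaves) {
        TT <- X$M[as.character(u), , drop = TRUE] +
          d[X$leaves, Y$leaves, drop = FALSE]  # rows m, cols k
        tmin <- apply(TT, 2L, min)
        tm <- X$leaves[apply(TT, 2L, which.min)]
        for (w in Y$leaves) {
          cost <- tmin + Y$M[, as.character(w)]
          k_i <- which.min(cost)
          cw <- cost[[k_i]]
          if (cw < M[as.character(u), as.character(w)]) {
            M[as.character(u), as.character(w)] <<- cw
            argm[as.character(u), as.character(w)] <<- tm[[k_i]]
            argk[as.character(u), as.character(w)] <<- Y$leaves[[k_i]]
          }
        }
      }
    }
    fill(A, B)
    fill(B, A)
    list(leaves = leaves, M = M, split = list(A = A, B = B, argm = argm,
                                              argk = argk))
  }

  reconstruct <- function(sol, u, w) {
    if (is.null(sol$split)) return(sol$leaves)
    A <- sol$split$A; B <- sol$split$B
    if (!(u %in% A$leaves)) { tmp <- A; A <- B; B <- tmp }
    m <- sol$split$argm[as.character(u), as.character(w)]
    k <- sol$split$argk[as.character(u), as.character(w)]
    c(reconstruct(A, u, m), reconstruct(B, k, w))
  }

  root <- solve_node(nrow(merge))
  best <- which(root$M == min(root$M), arr.ind = TRUE)[1L, ]
  u <- as.integer(rownames(root$M)[best[1]])
  w <- as.integer(colnames(root$M)[best[2]])
  reconstruct(root, u, w)
}

#' Branch-point marker genes
#'
#' At every junction of the dendrogram, each gene is scored by the
#' difference in fraction of positive cells (count > 0) between the two
#' branches; per-cluster fractions are averaged within each branch so
#' unequal cluster sizes do not dominate. The top `top_k` genes per side are
#' reported.
#'
#' @param m A [count_matrix()].
#' @param d A `taxonomy_dendrogram` over the same clusters.
#' @param labels Cluster label per cell.
#' @param top_k Genes reported per junction side.
#' @return `data.frame` with columns `junction`, `side` (`left`/`right`),
#'   `gene`, `delta` (left-minus-right difference, in \[-1, 1\]).
#' @export
branch_markers <- function(m, d, labels, top_k = 20) {
  stopifnot(inherits(d, "taxonomy_dendrogram"))
  labels <- align_labels(labels, cells(m))
  frac <- fraction_positive(m, labels)
  missing <- setdiff(unlist(lapply(d$junctions, function(j) c(j$left, j$right))),
                     colnames(frac))
  if (length(missing) > 0L)
    stopf("dendrogram clusters absent from labels: %s",
          paste(missing, collapse = ", "))
  out <- lapply(d$junctions, function(j) {
    delta <- rowMeans(frac[, j$left, drop = FALSE]) -
      rowMeans(frac[, j$right, drop = FALSE])
    kl <- utils::head(order(delta, decreasing = TRUE), top_k)
    kr <- utils::head(order(delta), top_k)
    rbind(
      data.frame(junction = j$id, side = "left", gene = rownames(frac)[kl],
                 delta = delta[kl], stringsAsFactors = FALSE),
      data.frame(junction = j$id, side = "right", gene = rownames(frac)[kr],
                 delta = delta[kr], stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
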