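# Neurotransmitter-class assignment by marker majority vote, and the
# score-ratio rule for doublet clusters.

#' Assign classes to clusters by marker majority vote
#'
#' Per cell, each marker set's mean normalized expression is computed and the
#' cell votes for the class with the highest mean (ties leave the cell
#' unvoted). Each cluster's class is the modal vote; clusters with no votes
#' are `"unassigned"`. The per-cluster per-class score (mean over cells of
#' the marker-set mean) is reported for the doublet rule.
#'
#' @param m A normalized [count_matrix()].
#' @param clusters Cluster label per cell.
#' @param marker_sets List of [marker_set()] objects (one class each).
#' @return A `class_assignment`: list with `clusters` (`data.frame` of
#'   cluster, class, doublet flag) and `scores` (clusters x classes matrix).
#' @export
assign_classes <- function(m, clusters, marker_sets = neuron_class_markers()) {
  x <- expr_values(m, "norm")
  clusters <- align_labels(clusters, colnames(x))
  classes <- vapply(marker_sets, `[[`, "", "class")
  if (anyDuplicated(classes)) stopf("marker sets must have distinct classes")

  cell_means <- vapply(marker_sets, function(ms) {
    g <- intersect(ms$genes, rownames(x))
    if (length(g) == 0L) return(numeric(ncol(x)))
    Matrix::colSums(x[g, , drop = FALSE]) / length(ms$genes)
  }, numeric(ncol(x)))
  colnames(cell_means) <- classes

  # per-cell vote: argmax class, ties or all-zero -> no vote
  top <- apply(cell_means, 1L, max)
  votes <- rep(NA_character_, ncol(x))
  voted <- top > 0 & apply(cell_means, 1L, function(v) sum(v == max(v)) == 1L)
  votes[voted] <- classes[max.col(cell_means[voted, , drop = FALSE])]

  lev <- sort(unique(clusters))
  scores <- t(vapply(lev, function(cl)
    colMeans(cell_means[clusters == cl, , drop = FALSE]),
    numeric(length(classes))))
  dimnames(scores) <- list(lev, classes)

  cluster_class <- vapply(lev, function(cl) {
    v <- votes[clusters == cl]
    v <- v[!is.na(v)]
    if (length(v) == 0L) "unassigned" else modal_label(v, classes)
  }, "")

  structure(list(clusters = data.frame(cluster = lev, class = cluster_class,
                                       doublet = FALSE,
                                       stringsAsFactors = FALSE),
                 scores = scores),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("class_assignment: %d clusters (%d doublet-flagged)\n",
              nrow(x$clusters), sum(x$clusters$doublet)))
  print(table(x$clusters$class))
  invisible(x)
}

#' Flag doublet clusters by the marker-score ratio rule
#'
#' A cluster is flagged when its top two class scores are within
#' `ratio_threshold` of each other (top/second < threshold), unless the two
#' classes form a permitted combination (by default VGLUT1 with VGLUT2).
#' A second score of zero never flags.
#'
#' @param a A `class_assignment` from [assign_classes()].
#' @param ratio_threshold Score ratio below which a cluster is a doublet.
#' @param allowed_pairs List of length-2 character vectors of permitted
#'   class combinations.
#' @return The `class_assignment` with its `doublet` column updated.
#' @export
call_doublet_clusters <- function(a, ratio_threshold = 2,
                                  allowed_pairs = list(c("VGLUT1", "VGLUT2"))) {
  stopifnot(inherits(a, "class_assignment"))
  allowed <- vapply(allowed_pairs,
                    function(p) paste(sort(p), collapse = "|"), "")
  flags <- apply(a$scores, 1L, function(v) {
    ord <- order(v, decreasing = TRUE)
    top <- v[ord[1]]
    second <- if (length(v) > 1L) v[ord[2]] else 0
    if (second <= 0) return(FALSE)
    pair <- paste(sort(colnames(a$scores)[ord[1:2]]), collapse = "|")
    (top / second < ratio_threshold) && !(pair %in% allowed)
  })
  a$clusters$doublet <- as.logical(flags)
  a
}
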