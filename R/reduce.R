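# Dimensionality reduction: PCA, batch correction of the projection,
# perplexity heuristic and the 2D t-SNE embedding.

#' PCA projection of selected features
#'
#' Projects cells into PC space from log2(x + 1)-transformed normalized
#' expression of the given features. When `n_pcs` is `NULL` the number of
#' PCs is the bending point of the explained-variance-versus-PC curve,
#' located by the chord criterion on the cumulative curve (the point where
#' the marginal explained variance falls below the average increment), which
#' is robust to a few dominant components hiding later structure.
#'
#' @param m A normalized [count_matrix()].
#' @param features Gene symbols to use (typically [selected_features()]).
#' @param n_pcs Number of PCs, or `NULL` for the elbow choice.
#' @param max_pcs Upper bound on computed PCs.
#' @return A list with `projection` (cells x PCs), `sdev` and `n_pcs`.
#' @export
pca_project <- function(m, features, n_pcs = NULL, max_pcs = 50) {
  x <- expr_values(m, "norm")
  missing <- setdiff(features, rownames(x))
  if (length(missing) > 0L)
    stopf("features absent from matrix: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  xm <- t(as.matrix(log2(x[features, , drop = FALSE] + 1)))
  k <- min(max_pcs, dim(xm) - 1L)
  pc <- stats::prcomp(xm, center = TRUE, scale. = FALSE, rank. = k)
  if (is.null(n_pcs)) {
    expl <- pc$sdev[seq_len(k)]^2
    n_pcs <- max(2L, chord_elbow(cumsum(expl)))
  }
  n_pcs <- min(n_pcs, ncol(pc$x))
  list(projection = pc$x[, seq_len(n_pcs), drop = FALSE],
       sdev = pc$sdev, n_pcs = n_pcs)
}

#' Correct batch structure in a PCA projection
#'
#' Aligns batches by mean-centering every component within each batch and
#' restoring the global component means, which removes location shifts
#' between batches while leaving within-batch geometry untouched. With a
#' single batch (or any batch of fewer than 3 cells, with a warning) the
#' projection passes through unchanged.
#'
#' @param projection Cells x PCs matrix.
#' @param batches Batch label per cell.
#' @return Adjusted projection of the same shape.
#' @export
correct_batches <- function(projection, batches) {
  projection <- as.matrix(projection)
  if (length(batches) != nrow(projection))
    stopf("one batch label per cell required")
  lev <- unique(batches)
  if (length(lev) < 2L) return(projection)
  sizes <- table(batches)
  if (any(sizes < 3L)) {
    warnf("batch(es) with fewer than 3 cells (%s); projection unchanged",
          paste(names(sizes)[sizes < 3L], collapse = ", "))
    return(projection)
  }
  centers <- colMeans(projection)
  out <- projection
  for (b in lev) {
    idx <- batches == b
    out[idx, ] <- scale(projection[idx, , drop = FALSE], center = TRUE,
                        scale = FALSE)
  }
  sweep(out, 2L, centers, `+`)
}

#' Choose t-SNE perplexity from local neighborhood structure
#'
#' For each cell, correlation distances to its nearest `k_max` neighbors are
#' sorted and the elbow of that curve gives a per-cell optimal neighbor
#' count; the perplexity is the median over cells, clipped to
#' \[5, n/4\].
#'
#' @param projection Cells x PCs matrix.
#' @param k_max Neighbors examined per cell.
#' @return A single perplexity value.
#' @export
choose_perplexity <- function(projection, k_max = 500) {
  projection <- as.matrix(projection)
  n <- nrow(projection)
  if (n < 10L) stopf("need at least 10 cells to choose a perplexity")
  k <- min(k_max, n - 1L)
  d <- correlation_dist(projection)
  opt_k <- vapply(seq_len(n), function(i) {
    di <- sort(d[i, -i], partial = k)[seq_len(k)]
    chord_elbow(sort(di))
  }, 1L)
  max(min(stats::median(opt_k), n / 4), 5)  # floor of 5 wins for tiny n
}

#' t-SNE embedding configuration
#'
#' Bundles the embedding parameters: correlation distance, Barnes-Hut theta
#' 0.5, learning rate n/12, exaggeration 20 within the pipeline, and the
#' final-visualization override (perplexity 100, exaggeration 5).
#'
#' @param theta Barnes-Hut accuracy parameter.
#' @param learning_rate Learning rate; `NULL` means cells/12.
#' @param exaggeration Early exaggeration factor.
#' @param perplexity Perplexity; `NULL` invokes [choose_perplexity()].
#' @param n_pcs Number of PCs feeding the embedding (recorded only).
#' @param final_viz If `TRUE`, override to perplexity 100, exaggeration 5.
#' @param max_iter Gradient-descent iterations.
#' @param seed Integer seed; the embedding is deterministic given it.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(theta = 0.5, learning_rate = NULL,
                             exaggeration = 20, perplexity = NULL,
                             n_pcs = NULL, final_viz = FALSE,
                             max_iter = 1000, seed = 0) {
  if (!is.null(perplexity) && perplexity < 2) stopf("perplexity must be >= 2")
  structure(list(theta = theta, learning_rate = learning_rate,
                 exaggeration = exaggeration, perplexity = perplexity,
                 n_pcs = n_pcs, final_viz = final_viz, max_iter = max_iter,
                 seed = seed),
            class = "embedding_config")
}

#' Embed cells in 2D by t-SNE
#'
#' Barnes-Hut t-SNE on the correlation distances of the (batch-corrected)
#' PCA projection, initialized from the first two PCs scaled to sd 1e-4.
#' Deterministic given `cfg$seed`.
#'
#' @param projection Cells x PCs matrix.
#' @param cfg An [embedding_config()].
#' @return Cells x 2 coordinate matrix (rownames preserved).
#' @export
embed_2d <- function(projection, cfg = embedding_config()) {
  stopifnot(inherits(cfg, "embedding_config"))
  projection <- as.matrix(projection)
  n <- nrow(projection)
  perp <- cfg$perplexity
  exagg <- cfg$exaggeration
  if (cfg$final_viz) {
    perp <- 100
    exagg <- 5
  }
  if (is.null(perp)) perp <- choose_perplexity(projection)
  if (n < 3 * perp + 1)
    stopf("too few cells (%d) for perplexity %g (need > 3 x perplexity)",
          n, perp)
  eta <- cfg$learning_rate %||% (n / 12)
  d <- correlation_dist(projection)
  y0 <- projection[, 1:2, drop = FALSE]
  y0 <- scale(y0, center = TRUE, scale = apply(y0, 2, stats::sd) / 1e-4)
  fit <- with_seed(cfg$seed,
    Rtsne::Rtsne(d, dims = 2, is_distance = TRUE, perplexity = perp,
                 theta = cfg$theta, eta = eta, exaggeration_factor = exagg,
                 Y_init = y0, max_iter = cfg$max_iter, pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE))
  coords <- fit$Y
  rownames(coords) <- rownames(projection)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}
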