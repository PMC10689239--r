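# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (loops, no shared code with the package) so that
# package results can be checked against a second, independent route.

# Build a count_matrix from a dense genes x cells matrix with minimal
# metadata. Timepoints/batches recycle over cells unless given.
toy_matrix <- function(counts, timepoint = "HC", batch = "A",
                       animal = "m1",
                       timepoints = c("HC", "2h", "8h", "24h", "recall")) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  meta <- data.frame(cell = colnames(counts),
                     animal = rep_len(animal, ncol(counts)),
                     timepoint = rep_len(timepoint, ncol(counts)),
                     batch = rep_len(batch, ncol(counts)))
  count_matrix(counts, meta, timepoints = timepoints)
}

# Naive per-cell activation flags: expr > theta (or > 0 when theta == 0).
bf_flags <- function(expr, theta) {
  flags <- matrix(FALSE, ncol(expr), nrow(expr),
                  dimnames = list(colnames(expr), rownames(expr)))
  for (cell in colnames(expr)) {
    for (g in rownames(expr)) {
      cut <- theta[[g]]
      flags[cell, g] <- if (cut > 0) expr[g, cell] > cut else expr[g, cell] > 0
    }
  }
  flags
}

# Naive F / S / IEG score per cluster (pooled HC baseline).
bf_tables <- function(flags, clusters, timepoints, hc = "HC") {
  tps <- unique(timepoints)
  out <- list()
  for (cl in sort(unique(clusters))) {
    Fm <- matrix(NA_real_, ncol(flags), length(tps),
                 dimnames = list(colnames(flags), tps))
    for (tp in tps) {
      idx <- which(clusters == cl & timepoints == tp)
      if (length(idx) == 0) next
      for (g in colnames(flags)) Fm[g, tp] <- mean(flags[idx, g])
    }
    S <- colSums(Fm)
    cfc <- setdiff(tps, hc)
    score <- if (is.na(S[hc])) NA_real_ else max(S[cfc] - S[hc], na.rm = TRUE)
    out[[cl]] <- list(F = Fm, S = S, score = score)
  }
  out
}

# Naive observed / expected / ratio table.
bf_obs_exp <- function(any_flag, clusters, timepoints) {
  rows <- list()
  for (cl in sort(unique(clusters))) {
    for (tp in unique(timepoints)) {
      idx <- clusters == cl & timepoints == tp
      exp_frac <- mean(any_flag[timepoints == tp])
      obs <- if (any(idx)) mean(any_flag[idx]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, timepoint = tp, observed = obs, expected = exp_frac,
        ratio = if (exp_frac > 0) obs / exp_frac else NA_real_)
    }
  }
  do.call(rbind, rows)
}

# Naive trapping-DE d statistic on log2(x + 1) normalized expression.
bf_trap_d <- function(norm, high_cells, low_cells) {
  vapply(rownames(norm), function(g) {
    mean(log2(norm[g, high_cells] + 1)) - mean(log2(norm[g, low_cells] + 1))
  }, 1)
}

# Naive branch delta: mean per-cluster positive fraction, left minus right.
bf_branch_delta <- function(counts, clusters, left, right) {
  frac <- function(g, cl) mean(counts[g, clusters == cl] > 0)
  vapply(rownames(counts), function(g) {
    mean(vapply(left, function(cl) frac(g, cl), 1)) -
      mean(vapply(right, function(cl) frac(g, cl), 1))
  }, 1)
}

# Naive Pearson correlation between two vectors.
bf_pearson <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# All leaf orders of an hclust tree reachable by flipping internal nodes.
flip_order <- function(merge, flip) {
  rec <- function(node) {
    if (node < 0) return(-node)
    a <- rec(merge[node, 1])
    b <- rec(merge[node, 2])
    if (flip[node]) c(b, a) else c(a, b)
  }
  rec(nrow(merge))
}
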