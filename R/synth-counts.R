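#' Generate a synthetic UMI count matrix with planted ground truth
#'
#' Draws a genes x cells UMI matrix under the design's negative-binomial
#' (gamma-Poisson) law. Type markers are enriched `marker_fold`-fold, engram
#' cells have the IEG panel (and any signature genes) scaled up, module genes
#' share a multiplicative log-normal latent factor in active groups, batch
#' effects multiply per-batch gene rates, and a fraction of extra cells are
#' cross-class doublets whose rates are the sum of two randomly drawn cells'
#' rates.
#'
#' @param design A [synth_design()].
#' @return A list with elements `matrix` (a [count_matrix()]) and `truth`, a
#'   `data.frame` with one row per cell (`cell`, `type`, `class`,
#'   `timepoint`, `batch`, `animal`, `activated`, `doublet`) carrying
#'   attributes `markers` (list of planted marker genes per type),
#'   `modules` (resolved module specification), `module_factors` (cells x
#'   modules latent factor values) and `engram_types`.
#' @export
generate_counts <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  prof <- synth_profiles(design)
  d <- design

  # cell table -------------------------------------------------------------
  tp_batches <- lapply(d$timepoints, function(tp)
    names(d$batch_map)[vapply(d$batch_map, function(x) tp %in% x, TRUE)])
  names(tp_batches) <- d$timepoints
  rows <- list()
  for (ty in prof$types$type) {
    for (tp in d$timepoints) {
      n <- d$cells_per_type_per_timepoint
      bs <- tp_batches[[tp]]
      batch <- rep(bs, length.out = n)  # HC split across its batches
      rows[[length(rows) + 1L]] <- data.frame(
        type = ty, class = prof$types$class[prof$types$type == ty],
        timepoint = tp, batch = sort(batch), stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  n_cells <- nrow(meta)
  meta$animal <- sprintf("%s_%s_m%d", meta$batch, meta$timepoint,
                         (seq_len(n_cells) %% 2L) + 1L)

  with_seed(d$seed + 1L, {
    lambda <- prof$L[, meta$type, drop = FALSE]

    # per-cell library size factor (log-normal, mean 1)
    s <- stats::rlnorm(n_cells, meanlog = -d$library_size_sdlog^2 / 2,
                       sdlog = d$library_size_sdlog)
    lambda <- sweep(lambda, 2L, s, `*`)

    # batch effects (per batch, per gene, log-normal)
    batches <- names(d$batch_map)
    eff <- matrix(exp(stats::rnorm(d$n_genes * length(batches), 0,
                                   d$batch_effect_sd)),
                  nrow = d$n_genes,
                  dimnames = list(prof$genes, batches))
    lambda <- lambda * eff[, meta$batch, drop = FALSE]

    # planted engram activation
    activated <- rep(FALSE, n_cells)
    panel <- intersect(ieg_panel(), prof$genes)
    for (e in d$engram_spec) {
      for (tp in names(e$prob)) {
        idx <- which(meta$type == e$type & meta$timepoint == tp)
        if (length(idx) == 0L) next
        act <- idx[stats::runif(length(idx)) < e$prob[[tp]]]
        activated[act] <- TRUE
        if (length(act) > 0L) {
          lambda[panel, act] <- lambda[panel, act] * (e$panel_fold %||% 5)
          sig <- intersect(e$signature %||% character(), prof$genes)
          if (length(sig) > 0L)
            lambda[sig, act] <- lambda[sig, act] *
              2^(e$signature_log2fc %||% 0)
        }
      }
    }

    # planted coexpression modules: shared multiplicative latent factor
    module_factors <- matrix(1, n_cells, length(prof$modules),
                             dimnames = list(NULL, names(prof$modules)))
    for (mn in names(prof$modules)) {
      mo <- prof$modules[[mn]]
      idx <- which(meta$type %in% mo$types & meta$timepoint %in% mo$timepoints)
      if (length(idx) == 0L) next
      f <- exp(mo$loading * stats::rnorm(length(idx)) - mo$loading^2 / 2)
      module_factors[idx, mn] <- f
      lambda[mo$genes, idx] <- sweep(lambda[mo$genes, idx, drop = FALSE],
                                     2L, f, `*`)
    }

    # doublets: sums of two random cells' rates, across classes
    n_doub <- round(d$doublet_rate * n_cells)
    doub_meta <- NULL
    if (n_doub > 0L) {
      a <- sample.int(n_cells, n_doub, replace = TRUE)
      b <- vapply(a, function(i) {
        other <- which(meta$class != meta$class[i])
        if (length(other) == 0L) other <- setdiff(seq_len(n_cells), i)
        other[sample.int(length(other), 1L)]
      }, 1L)
      lambda <- cbind(lambda, lambda[, a, drop = FALSE] +
                                lambda[, b, drop = FALSE])
      doub_meta <- data.frame(
        type = paste(meta$type[a], meta$type[b], sep = "+"),
        class = "doublet", timepoint = meta$timepoint[a],
        batch = meta$batch[a], animal = meta$animal[a],
        stringsAsFactors = FALSE)
    }

    total <- n_cells + n_doub
    cell_ids <- sprintf("cell%06d", seq_len(total))
    colnames(lambda) <- cell_ids
    counts <- matrix(stats::rnbinom(length(lambda), mu = as.numeric(lambda),
                                    size = 1 / d$dispersion),
                     nrow = d$n_genes, dimnames = dimnames(lambda))

    full_meta <- rbind(meta, doub_meta)
    full_meta$cell <- cell_ids
    rownames(full_meta) <- cell_ids

    truth <- data.frame(cell = cell_ids, type = full_meta$type,
                        class = full_meta$class,
                        timepoint = full_meta$timepoint,
                        batch = full_meta$batch, animal = full_meta$animal,
                        activated = c(activated, rep(FALSE, n_doub)),
                        doublet = c(rep(FALSE, n_cells), rep(TRUE, n_doub)),
                        stringsAsFactors = FALSE)
    attr(truth, "markers") <- prof$markers
    attr(truth, "modules") <- prof$modules
    attr(truth, "module_factors") <- module_factors
    attr(truth, "engram_types") <-
      vapply(d$engram_spec, function(e) e$type, "")

    m <- count_matrix(counts,
                      full_meta[, c("animal", "timepoint", "batch")],
                      timepoints = d$timepoints)
    list(matrix = m, truth = truth)
  })
}
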