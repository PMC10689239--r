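# Synthetic study design and shared expression profiles. The generator
# emulates the structure the downstream modules assume: three neurotransmitter
# classes with marker genes, several cell types per class, the five-timepoint
# fear-conditioning design collected in two batches (A: HC-8h-24h;
# B: HC-2h-recall), planted IEG-high engram subsets, planted coregulated gene
# modules, per-batch gene-level effects, cross-class doublets, and matched
# spatial targets.

#' Describe a synthetic dataset
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' design object. Counts are drawn from a negative binomial (gamma-Poisson)
#' law with shared dispersion; library sizes are log-normal around
#' `library_size_mean`; planted modules act through one multiplicative
#' log-normal latent factor per module.
#'
#' @param n_types_per_class Named counts of cell types per class
#'   (`GABA`, `VGLUT1`, `VGLUT2`, `NonNeuronal`).
#' @param cells_per_type_per_timepoint Cells simulated per type and timepoint.
#' @param timepoints Ordered timepoint labels.
#' @param batch_map Named list mapping batch label to the timepoints it
#'   contains. `HC` may appear in several batches; its cells are split evenly.
#' @param n_genes Total genes (named marker/panel genes plus filler genes).
#' @param markers_per_type Marker genes planted per type.
#' @param marker_fold Multiplicative enrichment of a type's markers.
#' @param class_marker_fold Enrichment of the class marker (Gad2/Slc17a7/
#'   Slc17a6) within its class; other classes express it at rate 0.
#' @param library_size_mean Mean UMI per cell.
#' @param library_size_sdlog Log-scale sd of the per-cell library size.
#' @param gene_abundance_sdlog Log-scale sd of baseline gene abundances;
#'   the default (2) reproduces the heavy skew of real UMI data, where most
#'   genes are detected in well under half of the cells.
#' @param dispersion Negative-binomial overdispersion phi (variance
#'   mu + phi mu^2), shared across genes.
#' @param engram_spec List of planted engrams; each entry is a list with
#'   `type`, `prob` (named timepoint -> activation probability), `panel_fold`
#'   (fold applied to the IEG panel in activated cells), and optionally
#'   `signature` (extra gene symbols) with `signature_log2fc`.
#' @param module_spec List of planted coexpression modules; each entry has
#'   `name`, `genes` (a count of filler genes to allocate, or gene symbols),
#'   `loading` (latent-factor log-scale sd), `types` and `timepoints` in
#'   which the factor is active.
#' @param batch_effect_sd Log-scale sd of per-batch per-gene effects.
#' @param doublet_rate Fraction of extra cells synthesized as cross-class
#'   doublets (sum of two random cells' rates).
#' @param marker_base_mean Baseline (off-type) mean count of planted marker
#'   genes, so that markers are detectable in their own type (as real
#'   cell-type markers are) while staying under the feature-selection
#'   detection gate elsewhere.
#' @param panel_base_mean,module_base_mean Baseline mean counts given to the
#'   IEG panel and to module genes so percentile and correlation statistics
#'   are exercised away from zero.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated `synth_design` list.
#' @export
synth_design <- function(n_types_per_class = c(GABA = 4, VGLUT1 = 4,
                                               VGLUT2 = 4, NonNeuronal = 0),
                         cells_per_type_per_timepoint = 60,
                         timepoints = c("HC", "2h", "8h", "24h", "recall"),
                         batch_map = list(A = c("HC", "8h", "24h"),
                                          B = c("HC", "2h", "recall")),
                         n_genes = 2000,
                         markers_per_type = 10,
                         marker_fold = 8,
                         class_marker_fold = 20,
                         library_size_mean = 6000,
                         library_size_sdlog = 0.3,
                         gene_abundance_sdlog = 2,
                         dispersion = 0.3,
                         engram_spec = list(),
                         module_spec = list(),
                         batch_effect_sd = 0.15,
                         doublet_rate = 0.02,
                         marker_base_mean = 0.5,
                         panel_base_mean = 3,
                         module_base_mean = 10,
                         seed = 0) {
  design <- list(n_types_per_class = n_types_per_class,
                 cells_per_type_per_timepoint = cells_per_type_per_timepoint,
                 timepoints = timepoints, batch_map = batch_map,
                 n_genes = n_genes, markers_per_type = markers_per_type,
                 marker_fold = marker_fold,
                 class_marker_fold = class_marker_fold,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog,
                 gene_abundance_sdlog = gene_abundance_sdlog,
                 dispersion = dispersion, engram_spec = engram_spec,
                 module_spec = module_spec,
                 batch_effect_sd = batch_effect_sd,
                 doublet_rate = doublet_rate,
                 marker_base_mean = marker_base_mean,
                 panel_base_mean = panel_base_mean,
                 module_base_mean = module_base_mean,
                 seed = as.integer(seed))
  class(design) <- "synth_design"
  validate_synth_design(design)
  design
}

validate_synth_design <- function(d) {
  known <- c("GABA", "VGLUT1", "VGLUT2", "NonNeuronal")
  if (!all(names(d$n_types_per_class) %in% known))
    stopf("unknown class in n_types_per_class: %s",
          paste(setdiff(names(d$n_types_per_class), known), collapse = ", "))
  if (sum(d$n_types_per_class) < 1L) stopf("design has no cell types")
  if (d$n_genes < 50L) stopf("n_genes must be at least 50")
  folds <- c(d$marker_fold, d$class_marker_fold,
             vapply(d$engram_spec, function(e) e$panel_fold %||% 5, 1))
  if (any(folds <= 0)) stopf("all fold changes must be > 0")
  if (d$doublet_rate < 0 || d$doublet_rate >= 1)
    stopf("doublet_rate must be in [0, 1)")
  if (d$dispersion <= 0) stopf("dispersion must be > 0")
  bad_tp <- setdiff(unlist(d$batch_map), d$timepoints)
  if (length(bad_tp) > 0L)
    stopf("batch_map contains unknown timepoint(s): %s",
          paste(bad_tp, collapse = ", "))
  uncovered <- setdiff(d$timepoints, unlist(d$batch_map))
  if (length(uncovered) > 0L)
    stopf("timepoint(s) not covered by batch_map: %s",
          paste(uncovered, collapse = ", "))
  type_ids <- design_type_ids(d)
  for (e in d$engram_spec) {
    if (is.null(e$type) || !e$type %in% type_ids)
      stopf("engram_spec type '%s' is not in the design", e$type %||% "<NULL>")
    if (is.null(e$prob) || is.null(names(e$prob)))
      stopf("engram_spec entries need a named 'prob' vector")
    if (any(e$prob < 0 | e$prob > 1))
      stopf("activation probabilities must be in [0, 1]")
    if (!all(names(e$prob) %in% d$timepoints))
      stopf("engram_spec prob names must be timepoints")
  }
  for (mo in d$module_spec) {
    bad <- setdiff(mo$types %||% character(), type_ids)
    if (length(bad) > 0L)
      stopf("module_spec type(s) not in design: %s", paste(bad, collapse = ", "))
  }
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Type identifiers, e.g. GABA_1 .. GABA_4, VGLUT1_1 ...
design_type_ids <- function(d) {
  unlist(lapply(names(d$n_types_per_class), function(cl) {
    k <- d$n_types_per_class[[cl]]
    if (k == 0L) character() else paste(cl, seq_len(k), sep = "_")
  }), use.names = FALSE)
}

# Deterministic assignment of types to spatial regions (round robin), shared
# by the spot and voxel generators so both targets agree with the truth.
assign_type_regions <- function(type_ids, n_regions) {
  regions <- paste0("R", seq_len(n_regions))
  stats::setNames(regions[((seq_along(type_ids) - 1L) %% n_regions) + 1L],
                  type_ids)
}

# Build the gene universe and per-type mean expression profiles. Seeded by
# design$seed so the count, spot and voxel generators share identical
# profiles. Returns genes, type table, rate matrix L (genes x types), marker
# map and the resolved module specification.
synth_profiles <- function(design) {
  d <- design
  with_seed(d$seed, {
    type_ids <- design_type_ids(d)
    classes <- sub("_[0-9]+$", "", type_ids)
    class_markers <- c(GABA = "Gad2", VGLUT1 = "Slc17a7", VGLUT2 = "Slc17a6")
    named <- unique(c(unname(class_markers), ieg_panel(),
                      if (any(classes == "NonNeuronal")) nonneuronal_markers()))
    module_named <- unlist(lapply(d$module_spec, function(mo)
      if (is.character(mo$genes)) mo$genes else character()))
    named <- unique(c(named, module_named))
    n_filler <- d$n_genes - length(named)
    if (n_filler < d$markers_per_type * length(type_ids) + 20L)
      stopf("n_genes too small for %d types x %d markers",
            length(type_ids), d$markers_per_type)
    filler <- sprintf("G%05d", seq_len(n_filler))
    gene_ids <- c(named, filler)

    # baseline rates: log-normal weights scaled to the target library size
    w <- stats::rlnorm(d$n_genes, meanlog = 0, sdlog = d$gene_abundance_sdlog)
    names(w) <- gene_ids
    lambda0 <- w / sum(w) * d$library_size_mean
    lambda0[ieg_panel()] <- d$panel_base_mean
    lambda0[unname(class_markers)] <- d$panel_base_mean

    # resolve modules: integer gene counts are allocated from filler genes
    pool <- filler
    markers <- list()
    for (ty in type_ids) {
      markers[[ty]] <- pool[seq_len(d$markers_per_type)]
      pool <- pool[-seq_len(d$markers_per_type)]
    }
    lambda0[unlist(markers)] <- d$marker_base_mean
    # engram signature genes must be expressed (the trapping DE rule only
    # evaluates genes with mean UMI > 1)
    for (e in d$engram_spec) {
      sig <- intersect(e$signature %||% character(), gene_ids)
      if (length(sig) > 0L) lambda0[sig] <- d$panel_base_mean
    }
    modules <- list()
    for (mo in d$module_spec) {
      genes_mo <- if (is.character(mo$genes)) mo$genes else {
        g <- pool[seq_len(mo$genes)]
        pool <- pool[-seq_len(mo$genes)]
        g
      }
      lambda0[genes_mo] <- d$module_base_mean
      modules[[mo$name %||% paste0("module", length(modules) + 1L)]] <-
        list(genes = genes_mo, loading = mo$loading %||% 0.42,
             types = mo$types %||% type_ids,
             timepoints = mo$timepoints %||% setdiff(d$timepoints, "HC"))
    }

    # per-type rate matrix
    L <- matrix(lambda0, nrow = d$n_genes, ncol = length(type_ids),
                dimnames = list(gene_ids, type_ids))
    for (i in seq_along(type_ids)) {
      ty <- type_ids[[i]]
      cl <- classes[[i]]
      L[markers[[ty]], i] <- L[markers[[ty]], i] * d$marker_fold
      for (cm_class in names(class_markers)) {
        cm <- class_markers[[cm_class]]
        L[cm, i] <- if (cm_class == cl) lambda0[cm] * d$class_marker_fold else 0
      }
      if (cl == "NonNeuronal") {
        L[nonneuronal_markers(), i] <- lambda0[nonneuronal_markers()] *
          d$class_marker_fold / 5
      }
    }
    list(genes = gene_ids,
         types = data.frame(type = type_ids, class = classes,
                            stringsAsFactors = FALSE),
         L = L, markers = markers, modules = modules)
  })
}
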