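# Configuration and pipeline orchestration. Every threshold and percentile
# used by the analysis lives in one config block, so the methods constants
# are defaults, not literals scattered through code.

#' Default analysis configuration
#'
#' One nested list holding QC thresholds, the normalization scale, exclusion
#' lists, the activity panel and its percentiles, module gene lists,
#' embedding and clustering parameters, the home-cage baseline mode, seeds,
#' and the synthetic-design parameters used by the demo pipeline.
#'
#' @return Named list (see [validate_config()] for the schema).
#' @export
default_config <- function() {
  list(
    qc = list(min_umi = 3000, min_genes = 2500,
              nonneuronal_min_umi = 2000, nonneuronal_min_genes = 1000),
    normalization = list(scale = NORMALIZATION_SCALE, norm = "l1"),
    exclusion = list(iegs = ieg_exclusion_genes(), sex = sex_genes(),
                     markers = nonneuronal_markers()),
    panel = list(genes = ieg_panel(), q_activation = 90, q_trap = 95,
                 q_enrichment = 99),
    modules = learning_module_sets(),
    embedding = list(theta = 0.5, exaggeration = 20, final_exaggeration = 5,
                     final_perplexity = 100, max_pcs = 50),
    clustering = list(min_pts = 10, eps = NULL, knn_k = 10,
                      merge_threshold = 0.995),
    engram = list(min_cluster_cells = 60, min_group_cells = 20,
                  hc_mode = "pooled", hc_key = "HC"),
    modulecorr = list(min_gene_cells = 200, min_cluster_per_tp = 20,
                      screen_min_cells = 5, screen_alpha = 0.01),
    photometry = list(pre = 5, post = 5, bin = 0.5),
    synth = list(n_types_per_class = c(GABA = 4, VGLUT1 = 4, VGLUT2 = 4,
                                       NonNeuronal = 0),
                 cells_per_type_per_timepoint = 40, n_genes = 500,
                 markers_per_type = 10, marker_fold = 8,
                 doublet_rate = 0.02),
    seed = 0
  )
}

#' Demo configuration for the synthetic pipeline
#'
#' [default_config()] carries the study-scale QC thresholds (3,000 UMI and
#' 2,500 detected genes per cell), which assume a transcriptome-wide gene
#' universe. The demo configuration keeps every analysis constant but scales
#' the QC gates to the small synthetic gene universe so the end-to-end
#' pipeline runs on generated data.
#'
#' @return A configuration list (see [default_config()]).
#' @export
demo_config <- function() {
  cfg <- default_config()
  cfg$qc$min_umi <- 2000
  cfg$qc$min_genes <- round(cfg$synth$n_genes * 0.2)
  cfg
}

#' Validate a configuration against the default schema
#'
#' Unknown keys (at the top level or inside any block) are rejected;
#' missing keys are filled with defaults.
#'
#' @param cfg Possibly partial configuration list.
#' @return The completed configuration.
#' @export
validate_config <- function(cfg) {
  template <- default_config()
  unknown_top <- setdiff(names(cfg), names(template))
  if (length(unknown_top) > 0L)
    stopf("unknown config key(s): %s", paste(unknown_top, collapse = ", "))
  for (block in names(cfg)) {
    if (is.list(template[[block]]) && !is.null(names(template[[block]])) &&
        block != "modules") {
      unknown <- setdiff(names(cfg[[block]]), names(template[[block]]))
      if (length(unknown) > 0L)
        stopf("unknown key(s) in config$%s: %s", block,
              paste(unknown, collapse = ", "))
      template[[block]][names(cfg[[block]])] <- cfg[[block]]
    } else {
      template[[block]] <- cfg[[block]]
    }
  }
  template
}

#' Read / write a configuration as YAML
#' @param path YAML file path.
#' @return [read_config()]: the validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg Configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the demo analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order — simulate, qc, cluster, engram,
#' corr (and optionally spatial, photometry) — on a synthetic dataset drawn
#' from `cfg$synth`, caching stage outputs under `outdir` so a rerun with
#' the same manifest reuses intermediates.
#'
#' @param cfg Configuration (see [default_config()]).
#' @param stages Subset of stages to run; upstream stages are loaded from
#'   cache or computed as needed.
#' @param outdir Output directory.
#' @return A run manifest: list with `config_hash`, `seed`, `stages`
#'   (output paths), `version`, `timestamp`.
#' @export
run_pipeline <- function(cfg = default_config(),
                         stages = c("simulate", "qc", "cluster", "engram",
                                    "corr"),
                         outdir = tempfile("scengram_run_")) {
  cfg <- validate_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cache <- function(name) file.path(outdir, paste0(name, ".rds"))
  have <- function(name) file.exists(cache(name))
  load_stage <- function(name) readRDS(cache(name))
  save_stage <- function(name, value) {
    saveRDS(value, cache(name))
    value
  }
  all_stages <- c("simulate", "qc", "cluster", "spatial", "engram", "corr",
                  "photometry")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L)
    stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  outputs <- list()

  need <- function(name) name %in% stages || !have(name)

  design <- do.call(synth_design, c(cfg$synth, list(seed = cfg$seed)))

  sim <- if (need("simulate")) {
    save_stage("simulate", generate_counts(design))
  } else load_stage("simulate")
  outputs$simulate <- cache("simulate")

  qc <- if (need("qc")) {
    keep <- filter_cells(sim$matrix, cfg$qc$min_umi, cfg$qc$min_genes)
    m <- subset_matrix(sim$matrix, cells = keep)
    m <- normalize_cells(m, scale = cfg$normalization$scale,
                         norm = cfg$normalization$norm)
    save_stage("qc", m)
  } else load_stage("qc")
  outputs$qc <- cache("qc")

  clus <- if (need("cluster")) {
    ranking <- rank_features(qc, excluded = c(cfg$exclusion$iegs,
                                              cfg$exclusion$sex,
                                              cfg$exclusion$markers))
    pca <- pca_project(qc, selected_features(ranking),
                       max_pcs = cfg$embedding$max_pcs)
    proj <- correct_batches(pca$projection, qc$cell_meta$batch)
    coords <- embed_2d(proj, embedding_config(
      theta = cfg$embedding$theta, exaggeration = cfg$embedding$exaggeration,
      seed = cfg$seed))
    cs <- cluster_embedding(coords, eps = cfg$clustering$eps,
                            min_pts = cfg$clustering$min_pts)
    labels <- reassign_outliers_knn(coords, cs$labels,
                                    k = cfg$clustering$knn_k)
    labels <- merge_similar_clusters(qc, stats::setNames(labels, cells(qc)),
                                     threshold = cfg$clustering$merge_threshold)
    res <- list(ranking = ranking, projection = proj, coords = coords,
                labels = stats::setNames(labels, cells(qc)))
    if (length(unique(labels)) > 1L) {
      res$dendrogram <- build_dendrogram(qc, res$labels)
      res$branch_markers <- branch_markers(qc, res$dendrogram, res$labels)
    }
    utils::write.table(
      data.frame(cell = cells(qc), cluster = res$labels,
                 tsne1 = coords[, 1], tsne2 = coords[, 2]),
      file.path(outdir, "clusters.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    save_stage("cluster", res)
  } else load_stage("cluster")
  outputs$cluster <- cache("cluster")

  if ("spatial" %in% stages) {
    st <- generate_spatial(design)
    feats <- shared_features(qc, st)
    means <- cluster_profiles(qc, clus$labels)
    sc <- correlate_profiles(means, st, feats)
    outputs$spatial <- save_and_path(outdir, "spatial",
                                     list(target = st, correlation = sc,
                                          regions = regionwise_summary(sc)))
  }

  eng <- if (need("engram")) {
    thr <- activation_thresholds(qc, cfg$panel$genes, cfg$panel$q_activation)
    fl <- flag_active(qc, thr)
    at <- activation_tables(fl, clus$labels[cells(qc)],
                            qc$cell_meta$timepoint,
                            hc_key = cfg$engram$hc_key,
                            batches = qc$cell_meta$batch,
                            hc_mode = cfg$engram$hc_mode,
                            min_cluster_cells = cfg$engram$min_cluster_cells,
                            min_group_cells = cfg$engram$min_group_cells)
    utils::write.table(at$score, file.path(outdir, "ieg_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    save_stage("engram", list(thresholds = thr, flags = fl, tables = at))
  } else load_stage("engram")
  outputs$engram <- cache("engram")

  if ("corr" %in% stages) {
    mst <- tryCatch(
      module_score_table(qc, clus$labels[cells(qc)], cfg$modules$IEG,
                         hc_key = cfg$engram$hc_key),
      error = function(e) NULL)
    if (!is.null(mst))
      utils::write.table(mst$clusters,
                         file.path(outdir, "correlation_scores.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    outputs$corr <- save_and_path(outdir, "corr", mst)
  }

  if ("photometry" %in% stages) {
    ph <- generate_photometry(seed = cfg$seed)
    det <- detrend_photometry(ph$trace)
    ar <- event_zscore(det$dff, ph$trace$time, ph$events,
                       pre = cfg$photometry$pre, post = cfg$photometry$post,
                       bin = cfg$photometry$bin)
    utils::write.table(ar$z, file.path(outdir, "photometry_z.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    outputs$photometry <- save_and_path(outdir, "photometry",
                                        list(aligned = ar))
  }

  manifest <- list(config_hash = rlang::hash(cfg), seed = cfg$seed,
                   stages = outputs,
                   version = as.character(utils::packageVersion("scEngram")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  manifest
}

save_and_path <- function(outdir, name, value) {
  p <- file.path(outdir, paste0(name, ".rds"))
  saveRDS(value, p)
  p
}
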