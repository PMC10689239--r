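# Voxel-atlas quality filtering and cluster-to-region calling.

#' Filter atlas genes by expression quality
#'
#' A gene is valid in the voxel atlas when it covers more than `min_voxels`
#' voxels (energy > 0), its maximum energy exceeds `min_energy`, and its
#' mean energy over all voxels exceeds `min_mean` (all strict inequalities).
#'
#' @param atlas A `spatial_target` in voxel mode.
#' @param min_voxels Coverage threshold.
#' @param min_energy Maximum-energy threshold.
#' @param min_mean Mean-energy threshold.
#' @return Character vector of valid gene symbols.
#' @export
filter_atlas_genes <- function(atlas, min_voxels = 30, min_energy = 5,
                               min_mean = 0.2) {
  stopifnot(inherits(atlas, "spatial_target"))
  if (atlas$mode != "voxels") stopf("atlas filter needs a voxel target")
  e <- atlas$expr
  coverage <- rowSums(e > 0)
  maxes <- apply(e, 1L, max)
  means <- rowMeans(e)
  rownames(e)[coverage > min_voxels & maxes > min_energy & means > min_mean]
}

#' Correlate cluster profiles with a voxel atlas and call regions
#'
#' Pearson correlation of cluster mean profiles with every voxel over the
#' quality-filtered features, followed by a per-cluster region call: the
#' region with the highest mean correlation.
#'
#' @param cluster_means Genes x clusters matrix of mean normalized
#'   expression.
#' @param atlas A `spatial_target` in voxel mode.
#' @param features Feature genes; they are intersected with
#'   [filter_atlas_genes()] output before correlating.
#' @return List with `correlation` (a `spatial_correlation`),
#'   `region_table` (clusters x regions mean rho) and `region_call`
#'   (`data.frame` cluster, region).
#' @export
correlate_atlas <- function(cluster_means, atlas, features) {
  stopifnot(inherits(atlas, "spatial_target"))
  valid <- filter_atlas_genes(atlas)
  use <- intersect(features, valid)
  if (length(use) < 3L)
    stopf("only %d features survive the atlas quality filter", length(use))
  sc <- correlate_profiles(cluster_means, atlas, use)
  tab <- regionwise_summary(sc)
  call <- data.frame(cluster = rownames(tab),
                     region = colnames(tab)[apply(tab, 1L, which.max)],
                     stringsAsFactors = FALSE, row.names = NULL)
  list(correlation = sc, region_table = tab, region_call = call)
}
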