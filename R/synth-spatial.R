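# Spatial targets: capture-spot matrices and voxel atlases, plus their
# synthetic generators.

#' Create a spatial target
#'
#' A common container for the two spatial modalities: Visium-style capture
#' spots (2D coordinates, per-spot counts) and atlas-style voxel grids
#' (3D coordinates, per-voxel in situ "energy" values).
#'
#' @param expr Nonnegative genes x units matrix (counts or energy).
#' @param coords `data.frame` with a `unit` column and `x`, `y` (and `z` for
#'   voxels) coordinates, one row per unit.
#' @param regions Region annotation per unit.
#' @param mode `"spots"` or `"voxels"`.
#' @param grid_shape Optional 3D extents for voxel targets.
#' @return A `spatial_target` object.
#' @export
spatial_target <- function(expr, coords, regions,
                           mode = c("spots", "voxels"), grid_shape = NULL) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  if (any(expr < 0)) stopf("spatial expression must be nonnegative")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stopf("expr needs gene rownames and unit colnames")
  if (!all(colnames(expr) %in% coords$unit))
    stopf("every unit needs coordinates")
  coords <- coords[match(colnames(expr), coords$unit), , drop = FALSE]
  if (length(regions) != ncol(expr))
    stopf("regions must annotate every unit")
  structure(list(expr = expr, coords = coords,
                 regions = as.character(regions), mode = mode,
                 grid_shape = grid_shape),
            class = "spatial_target")
}

#' @export
print.spatial_target <- function(x, ...) {
  cat(sprintf("spatial_target (%s): %d genes x %d units, %d regions\n",
              x$mode, nrow(x$expr), ncol(x$expr),
              length(unique(x$regions))))
  invisible(x)
}

#' Generate a synthetic capture-spot matrix
#'
#' Spots are laid out on an xy grid partitioned into contiguous regions; each
#' spot is a Poisson-noised "micro-bulk" mixture of the design's type mean
#' profiles, dominated by the types assigned to its region.
#'
#' @param design A [synth_design()].
#' @param n_spots Number of capture spots.
#' @param n_regions Number of spatial regions (must not exceed the number of
#'   types).
#' @param dominant_weight Total mixture weight given to the region's own
#'   types.
#' @param spot_depth Mean UMI per spot; the default (1.5 per gene) matches
#'   the per-gene capture depth of real spot data, keeping most genes
#'   sparse across spots.
#' @return A `spatial_target` (mode `"spots"`) with attributes `weights`
#'   (true types x spots mixture weights) and `type_regions` (named region
#'   per type).
#' @export
generate_spatial <- function(design, n_spots = 400, n_regions = 4,
                             dominant_weight = 0.85, spot_depth = NULL) {
  stopifnot(inherits(design, "synth_design"))
  prof <- synth_profiles(design)
  type_ids <- prof$types$type
  if (n_regions > length(type_ids))
    stopf("n_regions (%d) exceeds number of types (%d)", n_regions,
          length(type_ids))
  type_regions <- assign_type_regions(type_ids, n_regions)
  if (is.null(spot_depth)) spot_depth <- round(1.5 * design$n_genes)

  with_seed(design$seed + 2L, {
    nx <- ceiling(sqrt(n_spots))
    xy <- expand.grid(x = seq_len(nx), y = seq_len(nx))[seq_len(n_spots), ]
    # contiguous vertical bands, one per region
    band <- ceiling(xy$x / nx * n_regions)
    regions <- paste0("R", band)
    p_type <- sweep(prof$L, 2L, colSums(prof$L), `/`)  # unit-sum profiles

    weights <- matrix(0, length(type_ids), n_spots,
                      dimnames = list(type_ids, NULL))
    for (j in seq_len(n_spots)) {
      own <- names(type_regions)[type_regions == regions[[j]]]
      other <- setdiff(type_ids, own)
      w <- stats::setNames(numeric(length(type_ids)), type_ids)
      w[own] <- stats::rgamma(length(own), shape = 2)
      if (length(other) > 0L) {
        w[own] <- w[own] / sum(w[own]) * dominant_weight
        w[other] <- stats::rgamma(length(other), shape = 2)
        w[other] <- w[other] / sum(w[other]) * (1 - dominant_weight)
      } else {
        w[own] <- w[own] / sum(w[own])
      }
      weights[, j] <- w
    }
    mu <- (p_type %*% weights) * spot_depth
    expr <- matrix(stats::rpois(length(mu), as.numeric(mu)),
                   nrow = nrow(mu))
    unit_ids <- sprintf("spot%04d", seq_len(n_spots))
    dimnames(expr) <- list(prof$genes, unit_ids)
    colnames(weights) <- unit_ids
    st <- spatial_target(expr,
                         data.frame(unit = unit_ids, x = xy$x, y = xy$y),
                         regions, mode = "spots")
    attr(st, "weights") <- weights
    attr(st, "type_regions") <- type_regions
    st
  })
}

#' Generate a synthetic voxel atlas
#'
#' Builds per-gene 3D "energy" grids in which each type's marker genes are
#' elevated inside that type's region, and plants genes that deliberately
#' violate each atlas quality threshold (sparse coverage, low maximum energy,
#' low mean, all-zero) to exercise [filter_atlas_genes()].
#'
#' @param design A [synth_design()].
#' @param grid_shape Integer 3D extents; the grid must contain more than 40
#'   voxels so the planted quality violations are constructible.
#' @param n_regions Number of regions partitioning the grid along x.
#' @return A `spatial_target` (mode `"voxels"`) with attributes
#'   `invalid_genes` (named character vector: gene -> violated rule) and
#'   `type_regions`.
#' @export
generate_voxel_atlas <- function(design, grid_shape = c(8, 8, 6),
                                 n_regions = 4) {
  stopifnot(inherits(design, "synth_design"))
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stopf("grid_shape must be three positive extents")
  n_vox <- prod(grid_shape)
  if (n_vox <= 40L) stopf("grid too small (%d voxels); need > 40", n_vox)
  prof <- synth_profiles(design)
  type_ids <- prof$types$type
  if (n_regions > length(type_ids))
    stopf("n_regions (%d) exceeds number of types (%d)", n_regions,
          length(type_ids))
  type_regions <- assign_type_regions(type_ids, n_regions)

  with_seed(design$seed + 3L, {
    xyz <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                       z = seq_len(grid_shape[3]))
    band <- ceiling(xyz$x / grid_shape[1] * n_regions)
    regions <- paste0("R", band)

    energy <- matrix(stats::runif(design$n_genes * n_vox, 0.5, 8),
                     nrow = design$n_genes,
                     dimnames = list(prof$genes, NULL))
    for (ty in type_ids) {
      vox <- which(regions == type_regions[[ty]])
      energy[prof$markers[[ty]], vox] <-
        energy[prof$markers[[ty]], vox, drop = FALSE] + 10
    }

    # planted invalid genes, one per quality rule (last filler genes, which
    # are never used as markers or module genes)
    used <- unique(c(unlist(prof$markers),
                     unlist(lapply(prof$modules, `[[`, "genes"))))
    pool <- rev(setdiff(grep("^G", prof$genes, value = TRUE), used))
    invalid <- c(coverage = pool[[1]], max_energy = pool[[2]],
                 mean_energy = pool[[3]], all_zero = pool[[4]])
    energy[invalid[["coverage"]], ] <- 0
    energy[invalid[["coverage"]], sample.int(n_vox, 30L)] <- 7  # exactly 30
    energy[invalid[["max_energy"]], ] <- stats::runif(n_vox, 0.1, 4.5)
    lowmean <- numeric(n_vox)
    keep <- sample.int(n_vox, 36L)
    lowmean[keep] <- 0.05
    lowmean[keep[[1]]] <- 5.5  # coverage and max pass, mean fails
    energy[invalid[["mean_energy"]], ] <- lowmean
    energy[invalid[["all_zero"]], ] <- 0

    unit_ids <- sprintf("vox%05d", seq_len(n_vox))
    colnames(energy) <- unit_ids
    st <- spatial_target(energy,
                         data.frame(unit = unit_ids, x = xyz$x, y = xyz$y,
                                    z = xyz$z),
                         regions, mode = "voxels", grid_shape = grid_shape)
    attr(st, "invalid_genes") <- invalid
    attr(st, "type_regions") <- type_regions
    st
  })
}
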