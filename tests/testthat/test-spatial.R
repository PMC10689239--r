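make_target <- function(expr, regions = rep("R1", ncol(expr))) {
  spatial_target(expr,
                 data.frame(unit = colnames(expr),
                            x = seq_len(ncol(expr)), y = 1),
                 regions, mode = "spots")
}

test_that("profile-unit correlations match hand-computed Pearson values", {
  set.seed(51)
  means <- matrix(rexp(5 * 3), 5, 3,
                  dimnames = list(paste0("g", 1:5), paste0("k", 1:3)))
  expr <- matrix(rpois(5 * 4, 6), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("u", 1:4)))
  tg <- make_target(expr)
  sc <- correlate_profiles(means, tg, paste0("g", 1:5))
  norm_expr <- sweep(expr, 2, colSums(expr), `/`)
  for (k in 1:3) for (u in 1:4) {
    expect_equal(sc$rho[k, u], bf_pearson(means[, k], norm_expr[, u]))
  }
})

test_that("proportional units give rho 1; zero-variance units are NA", {
  means <- matrix(c(1, 5, 2, 9, 3), 5, 1,
                  dimnames = list(paste0("g", 1:5), "k1"))
  expr <- cbind(u1 = 3 * means[, 1], u2 = rep(4, 5))
  rownames(expr) <- paste0("g", 1:5)
  sc <- correlate_profiles(means, make_target(expr), paste0("g", 1:5))
  expect_equal(sc$rho["k1", "u1"], 1)
  expect_true(is.na(sc$rho["k1", "u2"]))  # undefined, not 0
  expect_error(correlate_profiles(means, make_target(expr), paste0("g", 1:2)),
               "3 features")
})

test_that("rho is invariant to per-unit affine rescaling", {
  set.seed(52)
  means <- matrix(rexp(8 * 2), 8, 2,
                  dimnames = list(paste0("g", 1:8), c("k1", "k2")))
  expr <- matrix(rpois(8 * 3, 5) + 1, 8, 3,
                 dimnames = list(paste0("g", 1:8), paste0("u", 1:3)))
  sc1 <- correlate_profiles(means, make_target(expr), paste0("g", 1:8))
  scaled <- sweep(expr, 2, c(2, 10, 0.5), `*`)  # per-unit rescaling
  sc2 <- correlate_profiles(means, make_target(scaled), paste0("g", 1:8))
  expect_equal(sc1$rho, sc2$rho)
})

test_that("region summaries average valid units per region", {
  means <- matrix(c(1, 2, 4, 1, 6, 2), 3, 2,
                  dimnames = list(paste0("g", 1:3), c("k1", "k2")))
  expr <- matrix(c(2, 4, 8, 1, 6, 3, 5, 5, 5, 9, 1, 4), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("u", 1:4)))
  tg <- make_target(expr, regions = c("Ra", "Ra", "Rb", "Rb"))
  sc <- correlate_profiles(means, tg, paste0("g", 1:3))
  tab <- regionwise_summary(sc)
  # manual average over the two regions; u3 is zero-variance (NA, skipped)
  expect_equal(tab["k1", "Ra"], mean(sc$rho["k1", 1:2]))
  expect_equal(tab["k1", "Rb"], sc$rho["k1", 4])
  # single region equals plain row means
  tg1 <- make_target(expr[, c(1, 2, 4)])
  sc1 <- correlate_profiles(means, tg1, paste0("g", 1:3))
  expect_equal(regionwise_summary(sc1)[, "R1"], rowMeans(sc1$rho))
})

test_that("dominant and weighted maps follow the stated rules", {
  rho <- rbind(k1 = c(0.9, 0.2, -0.1), k2 = c(0.1, 0.6, -0.4))
  sc <- structure(list(rho = rho, features = letters[1:3],
                       target_mode = "spots",
                       regions = rep("R1", 3),
                       coords = data.frame(unit = paste0("u", 1:3),
                                           x = 1:3, y = 1)),
                  class = "spatial_correlation")
  colors <- c(k1 = "#FF0000", k2 = "#0000FF")
  dom <- render_map(sc, "dominant", colors)
  expect_equal(dom$label, c("k1", "k2", "k1"))
  wtd <- render_map(sc, "weighted", colors, background = "#DDDDDD")
  # unit 1 blends 90% red / 10% blue
  mix <- grDevices::col2rgb(wtd$color[1]) / 255
  expect_lt(abs(mix[1, 1] - 0.9), 0.01)  # 8-bit hex rounding
  expect_lt(abs(mix[3, 1] - 0.1), 0.01)
  # all-nonpositive unit gets the background color
  expect_equal(wtd$color[3], "#DDDDDD")

  # single cluster: uniform dominant map
  sc1 <- sc
  sc1$rho <- rho[1, , drop = FALSE]
  expect_equal(unique(render_map(sc1, "dominant", colors["k1"])$label), "k1")

  # permuting cluster order permutes labels consistently
  sc_perm <- sc
  sc_perm$rho <- rho[c(2, 1), ]
  dom2 <- render_map(sc_perm, "dominant", colors[c(2, 1)])
  expect_equal(dom2$label, dom$label)
})

test_that("weighted colors are convex combinations", {
  set.seed(53)
  rho <- matrix(runif(4 * 10, -0.5, 1), 4, 10,
                dimnames = list(paste0("k", 1:4), NULL))
  sc <- structure(list(rho = rho, features = letters[1:3],
                       target_mode = "spots", regions = rep("R1", 10),
                       coords = data.frame(unit = paste0("u", 1:10),
                                           x = 1:10, y = 1)),
                  class = "spatial_correlation")
  wtd <- render_map(sc, "weighted")
  comps <- grDevices::col2rgb(wtd$color) / 255
  expect_true(all(comps >= 0 & comps <= 1))
})

test_that("shared features come from the intersection of both selections", {
  d <- synth_design(n_types_per_class = c(GABA = 3, VGLUT1 = 3, VGLUT2 = 2,
                                          NonNeuronal = 0),
                    cells_per_type_per_timepoint = 20, n_genes = 600,
                    doublet_rate = 0, seed = 18)
  sim <- generate_counts(d)
  m <- normalize_cells(sim$matrix)
  st <- generate_spatial(d, n_spots = 300, n_regions = 4)
  feats <- shared_features(m, st)
  expect_gte(length(feats), 20)
  mk <- unlist(attr(sim$truth, "markers"))
  expect_gt(mean(feats %in% mk), 0.5)  # planted markers dominate
  expect_false(any(feats %in% nonneuronal_markers()))
})

test_that("atlas gene filter applies strict thresholds", {
  n_vox <- 100
  e <- rbind(
    ok        = runif(n_vox, 0.5, 8),
    cov30     = c(rep(7, 30), rep(0, 70)),     # exactly 30 voxels: invalid
    low_max   = runif(n_vox, 0.1, 4.9),
    low_mean  = c(5.5, rep(0.05, 35), rep(0, 64)),
    all_zero  = rep(0, n_vox))
  colnames(e) <- sprintf("v%03d", 1:n_vox)
  at <- spatial_target(e, data.frame(unit = colnames(e), x = 1:n_vox,
                                     y = 1, z = 1),
                       rep("R1", n_vox), mode = "voxels")
  expect_equal(filter_atlas_genes(at), "ok")
  expect_error(filter_atlas_genes(make_target(e)), "voxel")
})

test_that("cluster regions are recovered from spots and voxels", {
  d <- synth_design(n_types_per_class = c(GABA = 3, VGLUT1 = 3, VGLUT2 = 2,
                                          NonNeuronal = 0),
                    cells_per_type_per_timepoint = 20, n_genes = 600,
                    doublet_rate = 0, seed = 18)
  sim <- generate_counts(d)
  m <- normalize_cells(sim$matrix)
  st <- generate_spatial(d, n_spots = 300, n_regions = 4)
  tr <- attr(st, "type_regions")
  feats <- shared_features(m, st)
  keep <- !sim$truth$doublet
  means <- cluster_profiles(subset_matrix(m, cells = sim$truth$cell[keep]),
                            sim$truth$type[keep])
  sc <- correlate_profiles(means, st, feats)
  tab <- regionwise_summary(sc)
  call <- colnames(tab)[apply(tab, 1, which.max)]
  expect_gte(mean(call == tr[rownames(tab)]), 0.9)

  at <- generate_voxel_atlas(d, grid_shape = c(8, 8, 6), n_regions = 4)
  ca <- correlate_atlas(means, at, feats)
  expect_gte(mean(ca$region_call$region == tr[ca$region_call$cluster]), 0.9)
  inv <- attr(at, "invalid_genes")
  expect_false(any(inv %in% ca$correlation$features))
})
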