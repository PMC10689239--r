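test_that("activation thresholds are interpolated percentiles over all cells", {
  # 10-cell toy, q = 90: compare against an independently coded
  # linear-interpolation percentile (type-7 formula)
  set.seed(61)
  counts <- matrix(rpois(3 * 10, 8), 3, 10,
                   dimnames = list(c("Arc", "Fos", "Bdnf"), paste0("c", 1:10)))
  m <- normalize_cells(toy_matrix(counts))
  thr <- activation_thresholds(m, panel = c("Arc", "Fos", "Bdnf"), q = 90)
  type7 <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  for (g in c("Arc", "Fos", "Bdnf"))
    expect_equal(unname(thr$theta[g]),
                 type7(as.numeric(m$norm[g, ]), 0.9))

  # gene zero in > q% of cells has threshold exactly 0 (19/20 zeros > 90%)
  counts2 <- matrix(rpois(2 * 20, 6) + 1, 2, 20,
                    dimnames = list(c("Arc", "Fos"), paste0("c", 1:20)))
  counts2["Arc", ] <- 0L
  counts2["Arc", 1] <- 5L
  m2 <- normalize_cells(toy_matrix(counts2))
  thr2 <- activation_thresholds(m2, panel = c("Arc", "Fos"), q = 90)
  expect_equal(unname(thr2$theta["Arc"]), 0)

  expect_error(activation_thresholds(m, panel = c("Arc", "Nope")), "Nope")
})

test_that("activation flags equal brute-force enumeration", {
  set.seed(62)
  counts <- matrix(rpois(8 * 40, 3), 8, 40,
                   dimnames = list(ieg_panel(), sprintf("c%02d", 1:40)))
  counts[1, ] <- 0L  # an all-zero panel gene exercises the theta = 0 rule
  counts <- rbind(counts, other = rep(2L, 40))
  m <- normalize_cells(toy_matrix(counts))
  thr <- activation_thresholds(m, q = 90)
  fl <- flag_active(m, thr)
  expected <- bf_flags(as.matrix(m$norm[ieg_panel(), ]), thr$theta)
  expect_equal(fl$flags, expected)
  expect_equal(fl$any, apply(expected, 1, any))
  # an all-zero cell is never active
  counts3 <- counts
  counts3[, 1] <- 0L
  counts3["other", 1] <- 1L
  m3 <- normalize_cells(toy_matrix(counts3))
  fl3 <- flag_active(m3, activation_thresholds(m3, q = 90))
  expect_false(fl3$any[[1]])
})

test_that("activation tables, S additivity and the IEG score formula", {
  # the published example: S = (HC .4, 2h 1.2, 8h .9, 24h .6, recall .5)
  # must score 0.8, and identical S scores 0
  set.seed(63)
  n_per <- 20
  tps <- c("HC", "2h", "8h", "24h", "recall")
  target_S <- c(HC = 0.4, `2h` = 1.2, `8h` = 0.9, `24h` = 0.6, recall = 0.5)
  # build flags directly: 8 genes, fraction S/8 per gene and timepoint
  flags <- matrix(FALSE, n_per * 5, 8,
                  dimnames = list(sprintf("c%03d", 1:(n_per * 5)),
                                  ieg_panel()))
  timepoints <- rep(tps, each = n_per)
  for (tp in tps) {
    k <- round(target_S[[tp]] / 8 * n_per)
    rows <- which(timepoints == tp)[seq_len(k)]
    flags[rows, ] <- TRUE
  }
  fl <- list(flags = flags, any = apply(flags, 1, any))
  at <- activation_tables(fl, rep("k1", nrow(flags)), timepoints,
                          min_cluster_cells = 1, min_group_cells = 1)
  expect_equal(at$S$k1, colSums(at$F$k1))             # S additivity
  expect_equal(unname(at$score$score), 0.8)
  # identical S across timepoints scores 0
  flags0 <- flags
  flags0[] <- FALSE
  flags0[seq(1, nrow(flags0), by = 2), ] <- TRUE
  fl0 <- list(flags = flags0, any = apply(flags0, 1, any))
  at0 <- activation_tables(fl0, rep("k1", nrow(flags0)), timepoints)
  expect_equal(unname(at0$score$score), 0)
  # F bounded, confidence mask
  expect_true(all(at$F$k1 >= 0 & at$F$k1 <= 1))
  expect_true(at0$score$low_confidence[1] == (n_per < 20 || n_per * 5 < 60))
})

test_that("activation tables match the brute-force oracle on toy matrices", {
  set.seed(64)
  n <- 50
  counts <- matrix(rpois(10 * n, 4), 10, n,
                   dimnames = list(c(ieg_panel(), "a", "b"),
                                   sprintf("c%02d", 1:n)))
  tps <- sample(c("HC", "2h", "8h", "24h", "recall"), n, replace = TRUE)
  clusters <- sample(c("k1", "k2"), n, replace = TRUE)
  m <- normalize_cells(toy_matrix(counts, timepoint = tps))
  thr <- activation_thresholds(m, q = 90)
  fl <- flag_active(m, thr)
  at <- activation_tables(fl, clusters, tps,
                          min_cluster_cells = 1, min_group_cells = 1)
  expected <- bf_tables(fl$flags, clusters, tps)
  for (cl in names(expected)) {
    expect_equal(at$S[[cl]][names(expected[[cl]]$S)], expected[[cl]]$S)
    expect_equal(at$score$score[at$score$cluster == cl],
                 expected[[cl]]$score)
  }
})

test_that("observed versus expected enrichment matches hand computation", {
  any_flag <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                FALSE, FALSE, FALSE)
  clusters <- rep(c("k1", "k2", "k3"), each = 4)
  tps <- rep(c("HC", "2h"), 6)
  got <- observed_vs_expected(any_flag, clusters, tps)
  exp_tab <- bf_obs_exp(any_flag, clusters, tps)
  got <- got[order(got$cluster, got$timepoint), ]
  exp_tab <- exp_tab[order(exp_tab$cluster, exp_tab$timepoint), ]
  expect_equal(got$observed, exp_tab$observed)
  expect_equal(got$expected, exp_tab$expected)
  expect_equal(got$ratio, exp_tab$ratio)

  # uniform activation: all ratios 1
  u <- observed_vs_expected(rep(c(TRUE, FALSE), 6), clusters, rep("HC", 12))
  expect_true(all(u$ratio == 1))

  # one cluster holding every flagged cell: ratio = 1 / cluster share
  flag2 <- c(rep(TRUE, 4), rep(FALSE, 8))
  o2 <- observed_vs_expected(flag2, clusters, rep("HC", 12))
  expect_equal(o2$ratio[o2$cluster == "k1"], 1 / (4 / 12))
})

test_that("fold-change dynamics behave at the boundaries", {
  set.seed(65)
  n <- 60
  counts <- matrix(rpois(9 * n, 5), 9, n,
                   dimnames = list(c(ieg_panel(), "x"), sprintf("c%02d", 1:n)))
  tps <- rep(c("HC", "2h"), each = n / 2)
  m <- normalize_cells(toy_matrix(counts, timepoint = tps))
  thr <- activation_thresholds(m, q = 50)
  fc <- fold_change_dynamics(m, thr, rep("k1", n), tps)
  expect_true(all(fc$fold_change[fc$timepoint == "HC"] == 1, na.rm = TRUE))
  # identical distributions: FC near 1
  expect_lt(max(abs(fc$fold_change[fc$timepoint == "2h"] - 1), na.rm = TRUE),
            0.5)
  # no qualifying cells at a timepoint: missing
  counts2 <- counts
  counts2[, tps == "2h"] <- 0L
  counts2["x", tps == "2h"] <- 1L
  m2 <- normalize_cells(toy_matrix(counts2, timepoint = tps))
  thr2 <- activation_thresholds(m2, q = 50)
  fc2 <- fold_change_dynamics(m2, thr2, rep("k1", n), tps)
  expect_true(all(is.na(fc2$fold_change[fc2$timepoint == "2h"])))
})

test_that("a planted 5x induction is recovered exactly in the fold change", {
  # deterministic toy: equal library sizes, so normalized = counts * 20;
  # positive HC cells average 11, positive 2h cells average 55 -> with
  # theta = 0 the conditional-mean fold change is (1100 + .1)/(220 + .1)
  n <- 20
  tps <- rep(c("HC", "2h"), each = n / 2)
  arc <- c(rep(0, 8), 10, 12, rep(0, 8), 50, 60)
  counts <- rbind(Arc = arc,
                  matrix(0, 7, n, dimnames = list(ieg_panel()[-1], NULL)),
                  filler = 1000 - arc)
  colnames(counts) <- sprintf("c%02d", 1:n)
  m <- normalize_cells(toy_matrix(counts, timepoint = tps))
  thr <- activation_thresholds(m, q = 50)  # theta = 0 for Arc (80% zeros)
  fc <- fold_change_dynamics(m, thr, rep("k1", n), tps)
  got <- fc$fold_change[fc$gene == "Arc" & fc$timepoint == "2h"]
  expect_equal(got, (55 * 20 + 0.1) / (11 * 20 + 0.1))
  expect_equal(got, 5, tolerance = 0.01)
})

test_that("the trapping-DE d statistic matches brute force", {
  set.seed(67)
  counts <- matrix(rpois(12 * 16, 5) + 1, 12, 16,
                   dimnames = list(c(ieg_panel(), paste0("g", 1:4)),
                                   sprintf("c%02d", 1:16)))
  m <- normalize_cells(toy_matrix(counts, timepoint = "2h"))
  any_flag <- stats::setNames(rep(c(TRUE, FALSE), 8), cells(m))
  res <- trap_de(m, any_flag, cells(m), min_side = 5)
  high <- cells(m)[any_flag]
  low <- cells(m)[!any_flag]
  expected <- bf_trap_d(as.matrix(m$norm), high, low)
  expect_equal(stats::setNames(res$table$d, res$table$gene), expected)
  expect_lte(nrow(res$top_up), 100)
  expect_true(all(res$top_up$mean_umi > 1))
  expect_error(trap_de(m, stats::setNames(rep(TRUE, 16), cells(m)),
                       cells(m)), "per side")
})

test_that("trapping DE recovers a planted activation signature", {
  sig <- sprintf("G%05d", 51:80)
  eng <- list(list(type = "GABA_1",
                   prob = c("2h" = 0.3, "8h" = 0.3, "24h" = 0.3,
                            "recall" = 0.3),
                   panel_fold = 5, signature = sig, signature_log2fc = 1.5))
  d <- synth_design(n_types_per_class = c(GABA = 1, VGLUT1 = 0, VGLUT2 = 0,
                                          NonNeuronal = 0),
                    cells_per_type_per_timepoint = 150, n_genes = 300,
                    markers_per_type = 5, engram_spec = eng,
                    doublet_rate = 0, seed = 3)
  sim <- generate_counts(d)
  m <- normalize_cells(sim$matrix)
  fl <- flag_active(m, activation_thresholds(m, q = 95))
  res <- trap_de(m, fl$any, cells(m)[m$cell_meta$timepoint != "HC"])
  expect_gte(mean(sig %in% head(res$top_up$gene, 50)), 0.9)
  # panel genes are up in IEG-high by construction
  expect_true(all(res$table$d[res$table$gene %in% ieg_panel()] > 0))
})

test_that("DE frequency ranking counts clusters above threshold", {
  fake <- function(d_values) {
    structure(list(table = data.frame(gene = names(d_values), d = d_values),
                   top_up = NULL, top_down = NULL, n_high = 10, n_low = 10),
              class = "trap_de_result")
  }
  res <- list(k1 = fake(c(a = 1.0, b = 0.6, c = 0.1)),
              k2 = fake(c(a = 0.9, b = 0.4, c = 0.2)),
              k3 = fake(c(a = 0.7, b = 0.8, c = -0.5)))
  fr <- de_frequency(res, d_threshold = 0.5)
  expect_equal(fr$gene, c("a", "b", "c"))        # 3, 2, 0 clusters
  expect_equal(fr$frequency, c(3L, 2L, 0L))
  # ties break alphabetically
  res2 <- list(k1 = fake(c(z = 1, b = 1)))
  expect_equal(de_frequency(res2)$gene, c("b", "z"))
})

test_that("group DE matches brute force and rejects overlap", {
  set.seed(68)
  counts <- matrix(rpois(6 * 20, 4) + 1, 6, 20,
                   dimnames = list(paste0("g", 1:6), sprintf("c%02d", 1:20)))
  m <- normalize_cells(toy_matrix(counts))
  A <- cells(m)[1:10]
  B <- cells(m)[11:20]
  gd <- group_de(m, A, B)
  expected <- bf_trap_d(as.matrix(m$norm), A, B)
  expect_equal(stats::setNames(gd$d, gd$gene), expected)
  expect_error(group_de(m, A, c(B, A[1])), "overlap")
  expect_error(group_de(m, character(), B), "nonempty")
})

test_that("a planted group shift is recovered by d", {
  set.seed(69)
  n <- 300
  counts <- matrix(rpois(20 * n, 8), 20, n,
                   dimnames = list(paste0("g", 1:20), sprintf("c%03d", 1:n)))
  counts[1:5, 1:(n / 2)] <- matrix(rpois(5 * n / 2, 16), 5)  # log2FC 1
  # a dominant filler keeps library sizes comparable across groups, so the
  # compositional shift does not leak into non-planted genes
  counts <- rbind(counts, filler = rpois(n, 3000))
  m <- normalize_cells(toy_matrix(counts))
  gd <- group_de(m, cells(m)[1:(n / 2)], cells(m)[(n / 2 + 1):n])
  expect_equal(mean(gd$d[1:5]), 1, tolerance = 0.3)
  expect_lt(max(abs(gd$d[6:20])), 0.3)
})
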