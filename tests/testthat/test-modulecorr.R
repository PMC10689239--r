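test_that("eligibility applies the strict gene and cluster gates", {
  set.seed(71)
  n <- 450
  counts <- matrix(0L, 3, n,
                   dimnames = list(c("in201", "in200", "sparse"),
                                   sprintf("c%03d", 1:n)))
  counts["in201", 1:201] <- 1L   # strictly more than 200 cells
  counts["in200", 1:200] <- 1L   # exactly 200: excluded
  counts["sparse", 1:10] <- 1L
  tps <- rep(c("HC", "2h", "8h", "24h", "recall"), length.out = n)
  m <- toy_matrix(counts, timepoint = tps)
  clusters <- rep("k1", n)
  clusters[seq(1, n, by = 2)] <- "k2"  # both clusters cover all timepoints
  el <- eligibility(m, clusters)
  expect_equal(el$genes, "in201")
  expect_true("k1" %in% el$clusters)

  # a cluster with 19 cells at one timepoint is excluded
  cl2 <- rep("k1", n)
  cl2[which(tps == "recall")[1:19]] <- "k3"  # k3: 19 recall cells only
  el2 <- eligibility(m, cl2)
  expect_false("k3" %in% el2$clusters)
})

test_that("pairwise correlations are exact and guarded", {
  set.seed(72)
  counts <- matrix(rpois(4 * 30, 6) + 1, 4, 30,
                   dimnames = list(paste0("g", 1:4), sprintf("c%02d", 1:30)))
  counts[2, ] <- counts[1, ]  # duplicated gene rows correlate at 1
  m <- normalize_cells(toy_matrix(counts))
  pc <- pairwise_correlation(m, paste0("g", 1:4), cells(m))
  expect_equal(pc$r["g1", "g2"], 1)
  expect_true(isSymmetric(pc$r))
  expect_equal(unname(diag(pc$r)), rep(1, 4))
  x <- as.matrix(m$norm)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(pc$r[i, j], bf_pearson(x[i, ], x[j, ]))
  }
  # zero-variance gene dropped with a warning; < 2 usable genes errors
  counts0 <- counts
  counts0[3, ] <- 5L
  m0 <- normalize_cells(toy_matrix(counts0))
  m0$norm[3, ] <- 7  # constant normalized values
  expect_warning(pc0 <- pairwise_correlation(m0, paste0("g", 1:4), cells(m0)),
                 "zero-variance")
  expect_false("g3" %in% rownames(pc0$r))
  expect_error(suppressWarnings(
    pairwise_correlation(m0, c("g3", "g3"), cells(m0))), "usable")
  expect_error(pairwise_correlation(m, paste0("g", 1:4), cells(m)[1:2]),
               "3 cells")
})

test_that("independent genes have small average correlation", {
  set.seed(73)
  counts <- matrix(rpois(10 * 100, 8), 10, 100,
                   dimnames = list(paste0("g", 1:10), sprintf("c%03d", 1:100)))
  m <- normalize_cells(toy_matrix(counts))
  pc <- pairwise_correlation(m, paste0("g", 1:10), cells(m))
  expect_lt(mean(abs(pc$r[upper.tri(pc$r)])), 0.15)
})

test_that("correlation p-values match the t-distribution oracle", {
  # closed-form check at a hand-computed point
  expect_equal(correlation_p(0.5, 12), 0.09785, tolerance = 1e-4)
  t_stat <- 0.5 * sqrt((12 - 2) / (1 - 0.25))
  expect_equal(t_stat, 1.8257, tolerance = 1e-4)
  expect_identical(correlation_p(0, 50), 1)

  # independent oracle: cor.test on random data
  set.seed(74)
  for (i in 1:100) {
    n <- sample(10:500, 1)
    x <- rnorm(n)
    y <- rnorm(n) + runif(1, -1, 1) * x
    r <- stats::cor(x, y)
    expect_equal(correlation_p(r, n), stats::cor.test(x, y)$p.value,
                 tolerance = 1e-10)
  }
  # grid of r and n values against 2 * pt(.)
  for (r in c(-0.99, -0.5, 0.2, 0.9, 0.99)) {
    for (n in c(5, 50, 1000, 10000)) {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      expect_equal(correlation_p(r, n),
                   2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
  # monotone decreasing in |r| at fixed n
  ps <- vapply(seq(0, 0.95, by = 0.05), correlation_p, 1, n = 30)
  expect_true(all(diff(ps) < 0))
  # |r| = 1 capped, not NaN
  expect_gt(correlation_p(1, 10), 0)
  expect_error(correlation_p(0.5, 3), "n >= 4")
})

test_that("null p-values are uniform (KS calibration)", {
  set.seed(75)
  ps <- replicate(1000, {
    x <- stats::rnbinom(100, mu = 10, size = 1 / 0.3)
    y <- stats::rnbinom(100, mu = 10, size = 1 / 0.3)
    correlation_p(stats::cor(x, y), 100)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("module scores follow the Fisher-z aggregation exactly", {
  # 3-gene toy: hand pipeline z-mean -> rbar -> t -> p
  r <- matrix(c(1, 0.5, 0.2, 0.5, 1, -0.1, 0.2, -0.1, 1), 3)
  ms <- module_score(r, n = 40)
  zbar <- mean(atanh(c(0.5, 0.2, -0.1)))
  rbar <- tanh(zbar)
  expect_equal(ms$rbar, rbar)
  expect_equal(ms$p, correlation_p(rbar, 40))
  expect_equal(ms$score, -log10(ms$p))

  # identity matrix (independent genes): rbar 0, score 0 exactly
  ms0 <- module_score(diag(3), n = 40)
  expect_identical(ms0$score, 0)

  # monotone in rbar at fixed n, and in n at fixed rbar > 0
  mk_r <- function(v) matrix(c(1, v, v, 1), 2)
  s_r <- vapply(c(0.1, 0.3, 0.5, 0.7), function(v)
    module_score(mk_r(v), 50)$score, 1)
  expect_true(all(diff(s_r) > 0))
  s_n <- vapply(c(10, 50, 200), function(n)
    module_score(mk_r(0.3), n)$score, 1)
  expect_true(all(diff(s_n) > 0))

  # duplicated genes (r = 1) hit the underflow floor instead of overflowing
  s_dup <- module_score(mk_r(1), 50)$score
  expect_gte(s_dup, 300)
  expect_lte(s_dup, 320)
  expect_error(module_score(matrix(1, 1, 1), 10), "off-diagonal")
})

test_that("cluster scores contrast conditioning against home-cage maxima", {
  expect_equal(cluster_score(c(1, 5, 2, 3), c(1, 2)), 3)
  expect_equal(cluster_score(c(2, 2), c(2, 2)), 0)
  expect_equal(cluster_score(c(0.5), c(2)), -1.5)  # may be negative
  expect_true(is.na(cluster_score(numeric(), c(1))))
  expect_true(is.na(cluster_score(c(NA_real_), c(1))))
})

test_that("planted modules rank above non-planted clusters", {
  mod <- list(list(name = "learn", genes = 10, loading = 0.42,
                   types = "GABA_1",
                   timepoints = c("2h", "8h", "24h", "recall")))
  ranked_ok <- 0
  for (seed in 1:10) {
    d <- synth_design(n_types_per_class = c(GABA = 2, VGLUT1 = 0, VGLUT2 = 0,
                                            NonNeuronal = 0),
                      cells_per_type_per_timepoint = 50, n_genes = 300,
                      markers_per_type = 5, module_spec = mod,
                      doublet_rate = 0, batch_effect_sd = 0, seed = seed)
    sim <- generate_counts(d)
    m <- normalize_cells(sim$matrix)
    mg <- attr(sim$truth, "modules")$learn$genes
    mst <- module_score_table(
      m, sim$truth$type, mg,
      elig = list(genes = mg, clusters = c("GABA_1", "GABA_2")))
    cl <- mst$clusters
    if (cl$cluster_score[cl$cluster == "GABA_1"] >
        cl$cluster_score[cl$cluster == "GABA_2"]) ranked_ok <- ranked_ok + 1
  }
  expect_gte(ranked_ok, 9)
})

test_that("the correlation screen counts per-group significance correctly", {
  set.seed(76)
  n <- 160
  z <- rnorm(n)
  target <- stats::rpois(n, exp(1.5 + 1.2 * z))
  partner <- stats::rpois(n, exp(1.5 + 1.2 * z))   # shares the factor
  indep <- stats::rpois(n, 3)
  counts <- rbind(tgt = target, par = partner, ind = indep,
                  lib = rep(50L, n))
  colnames(counts) <- sprintf("c%03d", 1:n)
  tps <- rep(c("2h", "8h"), each = n / 2)
  m <- normalize_cells(toy_matrix(counts, timepoint = tps))
  clusters <- rep("k1", n)
  scr <- gene_correlation_screen("tgt", m, clusters,
                                 elig = list(genes = rownames(counts),
                                             clusters = "k1"))
  expect_equal(scr$n_groups, 2)
  rk <- scr$ranking
  expect_false("tgt" %in% rk$gene[rk$frequency > 0])
  # brute-force recount per group
  x <- as.matrix(m$norm)
  for (g in c("par", "ind", "lib")) {
    cnt <- 0
    for (tp in c("2h", "8h")) {
      idx <- tps == tp
      if (sum(counts[g, idx] > 0) > 5 && stats::sd(x[g, idx]) > 0) {
        p <- correlation_p(bf_pearson(x[g, idx], x["tgt", idx]), sum(idx))
        if (p < 0.01) cnt <- cnt + 1
      }
    }
    expect_equal(rk$frequency[rk$gene == g], cnt)
  }
  expect_gte(rk$frequency[rk$gene == "par"], 1)
})
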