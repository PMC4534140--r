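scaled_cloud <- function(n = 20, p = 5, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(paste0("m", seq_len(n)), paste0("L", seq_len(p))))
}

test_that("dropping the normalization-dependent locus preserves order", {
  d <- sim_marker_dataset(81, n_a = 4, n_b = 4)
  red <- select_multivariate_loci(d$norm, "Cd36")
  expect_equal(ncol(red), 14)
  expect_false("Cd36" %in% colnames(red))
  expect_equal(colnames(red), setdiff(colnames(d$norm), "Cd36"))
  expect_error(select_multivariate_loci(d$norm, "NotALocus"), "NotALocus")
})

test_that("PCA satisfies its algebraic invariants", {
  x <- scaled_cloud(25, 6, seed = 2)
  pca <- run_pca(x)
  expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$variance_fractions) <= 1e-12))
  # score columns orthogonal
  cp <- crossprod(pca$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # full-rank reconstruction of the scaled matrix
  rec <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(rec - scale(x))), 1e-9)
  # deterministic sign convention: dominant loading positive
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  expect_error(run_pca(cbind(x, Konst = 1)), "Konst")
})

test_that("a planted separation direction dominates PC1", {
  set.seed(3)
  x <- scaled_cloud(30, 5, seed = 3)
  x[1:15, ] <- x[1:15, ] + 4  # shift all loci for one group
  pca <- run_pca(x)
  expect_gt(pca$variance_fractions[1], max(pca$variance_fractions[-1]))
  expect_true(all(pca$scores[1:15, 1] > 0) != all(pca$scores[16:30, 1] > 0) ||
                abs(mean(pca$scores[1:15, 1]) - mean(pca$scores[16:30, 1])) > 2)
})

test_that("split significance agrees with enumeration and is sign invariant", {
  # perfectly separated 5 + 5: shift every locus so PC1 carries the gap
  # even after per-column scaling
  x <- scaled_cloud(10, 4, seed = 4)
  x[1:5, ] <- x[1:5, ] + 50
  pca <- run_pca(x)
  labels <- rep(c("g1", "g2"), each = 5)
  cfg <- perm_config(2e4, 1, seed = 13)
  r <- split_significance(pca, labels, split_line("axis", 1), cfg)
  p_exact <- 2 / 252
  expect_lte(abs(r$p - p_exact), mc_band(p_exact, 2e4) + 1e-4)

  # flipping the PC sign or the diagonal slope leaves |T| unchanged
  flipped <- pca
  flipped$scores[, 1] <- -flipped$scores[, 1]
  expect_equal(split_significance(flipped, labels, split_line("axis", 1),
                                  perm_config(1e3, 1, seed = 14))$t_obs,
               r$t_obs, tolerance = 1e-12)
  d1 <- split_significance(pca, labels,
                           split_line("diagonal", components = c(1, 2),
                                      slope = 1),
                           perm_config(1e3, 1, seed = 15))
  d2 <- split_significance(flipped, labels,
                           split_line("diagonal", components = c(1, 2),
                                      slope = -1),
                           perm_config(1e3, 1, seed = 15))
  expect_equal(d1$t_obs, d2$t_obs, tolerance = 1e-12)

  # identical coordinates: observed statistic 0, p large
  degenerate <- pca
  degenerate$scores[, 1] <- 1
  expect_gte(split_significance(degenerate, labels, split_line("axis", 1),
                                perm_config(500, 1, seed = 16))$p, 0.5)
})

test_that("PC-covariate correlations hit the exact corners", {
  s <- c(3, 1, 4, 1.5, 9, 2.6)
  r <- pc_covariate_correlation(s, s)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  r2 <- pc_covariate_correlation(s, -s^3)  # anti-monotone, nonlinear
  expect_equal(r2$spearman_rho, -1)
  expect_error(pc_covariate_correlation(s, rep(1, 6)), "variance")
  expect_error(pc_covariate_correlation(1:3, 1:3), "4 paired")
})

test_that("MANOVA reduces to ANOVA univariately and matches Hotelling T2", {
  set.seed(17)
  y <- rnorm(20)
  g <- rep(c("a", "b"), 10)
  m1 <- manova_test(matrix(y, ncol = 1), g)
  expect_equal(m1$p, anova(lm(y ~ factor(g)))$`Pr(>F)`[1], tolerance = 1e-9)

  x <- matrix(rnorm(30 * 4), 30)
  g2 <- rep(c("a", "b"), c(17, 13))
  m2 <- manova_test(x, g2)
  expect_equal(m2$p, hotelling_p(x, g2), tolerance = 1e-9)
  expect_s3_class(m2, "manova_result")
  # Wilks option agrees with Pillai for two groups
  expect_equal(manova_test(x, g2, "Wilks")$p, m2$p, tolerance = 1e-9)
  expect_error(manova_test(matrix(rnorm(10 * 9), 10), rep(c("a", "b"), 5)),
               "loci")
})

test_that("MANOVA detects a planted multivariate mean shift", {
  # 1 pooled-sd shift on 6 of 14 loci at n = 24 vs 15: the noncentral-F
  # power of the equivalent Hotelling test (ncp = 24*15/39 * 6 = 55.4,
  # df = 14, 24) is 0.93 at alpha = 0.01, so nearly all replicates reject
  set.seed(18)
  hits <- replicate(40, {
    x <- matrix(rnorm(39 * 14), 39)
    x[25:39, 1:6] <- x[25:39, 1:6] + 1
    manova_test(x, rep(c("a", "b"), c(24, 15)))$p < 0.01
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Ward clustering recovers well-separated clouds and the exact merge order", {
  x <- scaled_cloud(12, 3, seed = 19)
  x[7:12, ] <- x[7:12, ] + 30
  hc <- ward_cluster(x, scale = FALSE)
  expect_equal(unname(cutree(hc, 2)), rep(1:2, each = 6))
  expect_true(all(diff(hc$height) >= -1e-9))

  # exhaustive minimum-variance oracle on small instances
  for (s in 20:23) {
    y <- scaled_cloud(6, 2, seed = s)
    hc2 <- ward_cluster(y, scale = FALSE)
    expect_equal(hclust_partitions(hc2), ward_bruteforce_partitions(y))
  }

  # invariance of the 2-cluster cut to row order
  perm <- sample(nrow(x))
  hc3 <- ward_cluster(x[perm, ], scale = FALSE)
  m1 <- cutree(hc, 2)
  m3 <- cutree(hc3, 2)[rownames(x)]
  expect_true(all((m1 == m1[1]) == (m3 == m3[1])))

  expect_error(ward_cluster(x[c(1, 1), ]), "unique")
  # legacy ward_d variant runs and produces a valid tree
  expect_s3_class(ward_cluster(x, variant = "ward_d", scale = FALSE), "hclust")
})

test_that("dendrograms export to Newick with heights as branch lengths", {
  x <- scaled_cloud(8, 3, seed = 24)
  hc <- ward_cluster(x, scale = FALSE)
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(x))
})

test_that("deepest-split tests behave on aligned, constant and enumerable cases", {
  x <- scaled_cloud(10, 4, seed = 25)
  x[6:10, ] <- x[6:10, ] + 20
  hc <- ward_cluster(x, scale = FALSE)

  # constant variable: statistic 0
  r0 <- deepest_split_test(hc, rep(1, 10), perm_config(500, 1, seed = 26))
  expect_gte(r0$perm_p, 0.5)

  # variable perfectly aligned with the 5+5 split: exact p = 2/252
  v <- as.numeric(cutree(hc, 2) == 2)
  r1 <- deepest_split_test(hc, v + rnorm(10, 0, 1e-6),
                           perm_config(2e4, 1, seed = 27))
  expect_lte(abs(r1$perm_p - 2 / 252), mc_band(2 / 252, 2e4) + 1e-4)
  expect_equal(sort(r1$cluster_sizes), c(5, 5))

  # Welch companion omitted when undefined, reported otherwise
  r2 <- deepest_split_test(hc, rnorm(10), perm_config(500, 1, seed = 28))
  expect_false(r2$welch_omitted)
  expect_true(r2$welch_p >= 0 && r2$welch_p <= 1)
  expect_error(deepest_split_test(hc, 1:5), "per tree leaf")
})
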