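test_that("Kruskal-Wallis matches the hand example and base R on random data", {
  kw <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kruskal_wallis(list(a = rep(2, 3), b = rep(2, 4)))$H, 0)
  set.seed(41)
  for (i in 1:100) {
    g <- lapply(seq_len(sample(2:5, 1)), function(j)
      sample(1:12, sample(3:8, 1), replace = TRUE))
    ref <- stats::kruskal.test(g)
    mine <- kruskal_wallis(g)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("Dunn post hoc reproduces the hand-computed example", {
  d <- dunn_posthoc(list(g1 = 1:3, g2 = 4:6, g3 = 7:9))
  row13 <- d[d$group1 == "g1" & d$group2 == "g3", ]
  expect_equal(abs(row13$z), 6 / sqrt(5), tolerance = 1e-12)
  expect_equal(row13$p_raw, 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-12)
  expect_equal(row13$p_holm, 3 * 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-12)
  expect_true(all(d$p_holm >= d$p_raw))
})

test_that("Dunn on identical groups gives z = 0 and adjusted p = 1", {
  d <- dunn_posthoc(list(a = rep(1, 4), b = rep(1, 5), c = rep(1, 3)))
  expect_equal(d$z, rep(0, 3))
  expect_equal(d$p_holm, rep(1, 3))
})

test_that("Holm and BH match their defining examples and p.adjust", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_bonferroni(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(holm_bonferroni(p), p.adjust(p, "holm"))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))
    expect_true(all(holm_bonferroni(p) >= p))
    expect_true(all(bh_fdr(p) >= p))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(-0.1), "\\[0, 1\\]")
})

test_that("permutation Spearman: exhaustive example and determinism", {
  s <- spearman_perm(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(s$rho, 0.8)
  expect_equal(s$p_perm, 1 / 3)
  expect_true(s$exhaustive)
  expect_equal(spearman_perm(1:5, (1:5)^3)$rho, 1)    # monotone map

  set.seed(43)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  a <- spearman_perm(x, y, n_perm = 500, seed = 7)
  b <- spearman_perm(x, y, n_perm = 500, seed = 7)
  c2 <- spearman_perm(x, y, n_perm = 2000, seed = 99)
  expect_identical(a$p_perm, b$p_perm)
  expect_false(a$exhaustive)
  expect_lt(abs(a$p_perm - c2$p_perm), 0.05 + 3 * sqrt(0.25 / 500))
  expect_error(spearman_perm(1:5, rep(2, 5)), "constant")
})

test_that("Monte Carlo permutation p converges to the exhaustive value", {
  set.seed(44)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  exact <- spearman_perm(x, y, n_perm = factorial(5))
  expect_true(exact$exhaustive)
  mc <- spearman_perm(x, y, n_perm = 119, seed = 3)   # force MC branch
  expect_false(mc$exhaustive)
  mc_big <- mean(vapply(1:20, function(s)
    spearman_perm(x, y, n_perm = 119, seed = s)$p_perm, numeric(1)))
  expect_equal(mc_big, exact$p_perm, tolerance = 0.08)
})

test_that("clinical correlation matrix has the right shape and detects coupling", {
  feats <- tiny_features()$features
  clin <- tiny_cohort()$clinical
  cc <- clinical_correlations(feats, clin, n_perm = 200, seed = 1)
  expect_equal(nrow(cc), length(feature_names()) * 2L)
  expect_setequal(unique(cc$clinical), c("baseline_bfmdrs", "percent_change"))
  expect_true(all(cc$p_fdr >= cc$p_perm - 1e-12))
  # perfectly coupled synthetic feature
  med <- aggregate(feats["theta_frac"], by = list(patient_id = feats$patient_id),
                   FUN = median)
  clin2 <- data.frame(patient_id = med$patient_id,
                      bfmdrs_pre = 10 + 100 * med$theta_frac,
                      percent_change = 50)
  feats2 <- feats; feats2$coupled <- feats2$theta_frac
  cc2 <- clinical_correlations(feats2, clin2, features = "coupled",
                               n_perm = 500, seed = 1)
  expect_equal(cc2$rho[cc2$clinical == "baseline_bfmdrs"], 1)
  expect_error(clinical_correlations(feats[feats$patient_id == "SIM01", ],
                                     clin[1, , drop = FALSE]), "3 patients")
})

test_that("depth correlations: identity feature, recovery, and null", {
  feats <- tiny_features()$features
  feats$depth_copy <- feats$normalized_depth
  dc <- depth_correlations(feats, features = "depth_copy", n_perm = 200)
  expect_true(all(abs(dc$rho - 1) < 1e-12))

  # programmed linear gradient recovered at n = 50
  set.seed(45)
  tab <- data.frame(patient_id = "P1", group = "VPS16",
                    normalized_depth = runif(50), in_gpi = TRUE)
  tab$beta_alpha_ratio <- 2 + 1.5 * tab$normalized_depth + rnorm(50, 0, 0.3)
  dc2 <- depth_correlations(tab, features = "beta_alpha_ratio", n_perm = 1000)
  expect_gt(dc2$rho, 0)
  expect_lte(dc2$p_fdr, 0.05)

  # shuffled depths: significance near nominal over 100 null draws
  set.seed(46)
  hits <- mean(vapply(1:100, function(i) {
    tab$y <- rnorm(50)
    depth_correlations(tab, features = "y", n_perm = 200, seed = i)$p_perm <= 0.05
  }, logical(1)))
  expect_gte(hits, 0.0)
  expect_lte(hits, 0.11)

  # insufficient data flagged missing, not an error
  small <- tab[1:2, ]
  dcm <- depth_correlations(small, features = "beta_alpha_ratio")
  expect_true(is.na(dcm$rho))
})

test_that("mixed model recovers a programmed depth slope", {
  tab <- simulate_lmm_table(seed = 47, slope = 0.5)
  r <- lmm_depth_effect(tab, "y")
  expect_gt(r$slope, 0.4); expect_lt(r$slope, 0.6)
  expect_lt(r$p, 0.01)
  # zero random variance, zero slope, pure noise
  tab0 <- simulate_lmm_table(seed = 48, slope = 0, sd_pat = 0)
  r0 <- lmm_depth_effect(tab0, "y")
  expect_lt(abs(r0$slope), 0.05)
})

test_that("LMM family output is Holm-adjusted and ordered", {
  tab <- simulate_lmm_table(seed = 49, slope = 0.3)
  tab$y2 <- rnorm(nrow(tab))
  out <- lmm_depth_effects(tab, features = c("y", "y2"))
  expect_equal(nrow(out), 2L)
  expect_true(all(out$p_holm >= out$p))
})
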