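test_that("rectification is full-wave symmetric with zero mean", {
  set.seed(31)
  x <- rnorm(5000)
  e <- rectify_demean(x)
  expect_identical(e, rectify_demean(-x))
  expect_lt(abs(mean(e)), 1e-9 * sqrt(mean(e^2)))
})

test_that("rectified sine has mean 2A/pi and dominant residual at 2f", {
  fs <- 1000; A <- 2.5
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- A * sin(2 * pi * 7 * t)
  expect_equal(mean(abs(x)), 2 * A / pi, tolerance = 1e-3)
  e <- rectify_demean(x)
  sp <- Mod(fft(e))[1:2000]                 # bins at 0.1 Hz spacing
  f_peak <- (which.max(sp) - 1) * fs / length(e)
  expect_equal(f_peak, 14, tolerance = 0.2) # 2f component dominates
})

test_that("Welch PSD has exactly 1/3 Hz spacing and satisfies Parseval", {
  x <- white_60s()
  p <- estimate_psd(x, 1000)
  expect_equal(p$df, 1 / 3)
  expect_equal(diff(p$freqs), rep(1 / 3, length(p$freqs) - 1))
  expect_gt(sum(p$power) * p$df / var(x), 0.95)
  expect_lt(sum(p$power) * p$df / var(x), 1.05)
  expect_error(estimate_psd(rnorm(2000), 1000), "duration")
})

test_that("a pure sine concentrates its power at its frequency", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 10 * t)
  p <- estimate_psd(s, fs)
  near <- abs(p$freqs - 10) <= 0.5
  expect_gte(sum(p$power[near]) / sum(p$power), 0.95)
  expect_equal(sum(p$power) * p$df, 0.5, tolerance = 0.02)
})

test_that("PSD normalization yields unit integral and scale invariance", {
  x <- white_60s()
  pn <- normalize_psd(estimate_psd(x, 1000))
  expect_equal(sum(pn$power) * pn$df, 1, tolerance = 1e-9)
  pn7 <- normalize_psd(estimate_psd(7 * x, 1000))
  expect_equal(pn$power, pn7$power, tolerance = 1e-9)
  expect_error(normalize_psd(estimate_psd(x, 1000), lo = 2, hi = 600), "cover")
})

test_that("white envelope band fractions approximate bandwidth ratios", {
  x <- white_60s()
  bw <- c(theta = 4, alpha = 4, beta = 18, gamma = 70)
  for (b in names(GPI_BANDS)) {
    fr <- band_power_fraction(x, 1000, b)
    expect_equal(fr, bw[[b]] / 198, tolerance = 0.15)
  }
  pn <- normalize_psd(estimate_psd(x, 1000))
  for (b in names(GPI_BANDS))
    expect_equal(band_fraction_psd(pn, b), bw[[b]] / 198, tolerance = 0.15)
})

test_that("a 6 Hz tone 20 dB above noise owns the theta band", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(32)
  e <- sin(2 * pi * 6 * t) + rnorm(length(t), sd = 0.0707)  # ~ -20 dB power
  expect_gte(band_power_fraction(e, fs, "theta"), 0.9)
})

test_that("four band fractions sum to at most 1 plus roll-off tolerance", {
  set.seed(33)
  for (i in 1:5) {
    mod <- runif(4, 0, 0.5)
    names(mod) <- names(GPI_BANDS)
    g <- generate_recording_signal(2000, 8, mod, seed = 100 + i)
    env <- decimate_envelope(rectify_demean(g$samples), 2000)
    s <- sum(vapply(names(GPI_BANDS), function(b)
      band_power_fraction(env$samples, env$fs, b), numeric(1)))
    expect_lte(s, 1 + 0.02)
  }
})

test_that("filter-domain and PSD-integration fractions agree within 20%", {
  x <- white_60s()
  pn <- normalize_psd(estimate_psd(x, 1000))
  for (b in c("theta", "beta", "gamma")) {
    a <- band_power_fraction(x, 1000, b)
    p <- band_fraction_psd(pn, b)
    expect_lt(abs(a - p) / p, 0.20)
  }
})

test_that("band ratios are fraction quotients with NA on zero denominators", {
  expect_equal(unname(band_ratios(c(theta = 0.1, alpha = 0.1, beta = 0.1))),
               c(1, 1, 1))
  r <- band_ratios(c(theta = 0.04, alpha = 0.03, beta = 0.12))
  expect_equal(unname(r["beta_theta_ratio"]), 3.0)
  expect_equal(unname(r["beta_alpha_ratio"]), 4.0)
  expect_equal(unname(r["beta_alpha_ratio"]),
               unname(r["beta_theta_ratio"] / r["alpha_theta_ratio"]),
               tolerance = 1e-12)
  r0 <- band_ratios(c(theta = 0, alpha = 0.1, beta = 0.1))
  expect_true(is.na(r0["alpha_theta_ratio"]))
})

test_that("baseline elevation is 1 on flat spectra and robust to bumps", {
  flat <- structure(list(freqs = seq(2, 200, by = 1 / 3),
                         power = rep(1, length(seq(2, 200, by = 1 / 3))),
                         df = 1 / 3), class = "mer_psd")
  flat <- normalize_psd(flat)
  for (b in names(GPI_BANDS))
    expect_equal(baseline_elevation(flat, b), 1, tolerance = 1e-9)
  bump <- flat
  th <- bump$freqs >= 4 & bump$freqs < 8
  bump$power[th] <- bump$power[th] * 3
  bump <- normalize_psd(bump)
  expect_equal(baseline_elevation(bump, "theta"), 3, tolerance = 1e-6)
})

test_that("theta/alpha elevation exceeds 1 on dystonia-like cohorts", {
  feats <- tiny_features()$features
  expect_gt(median(feats$theta_elev), 1)
  expect_gt(median(feats$alpha_elev), 1)
})

test_that("feature extraction is deterministic and scale invariant", {
  g <- generate_recording_signal(2000, 8, c(theta = 0.4, alpha = 0.2,
                                            beta = 0.1, gamma = 0.1), seed = 9)
  rec <- mer_recording("p", "SGCE", "t", 1, g$samples, 2000)
  f1 <- extract_features(rec)
  f2 <- extract_features(rec)
  expect_identical(f1, f2)
  for (k in c(0.1, 10)) {
    reck <- mer_recording("p", "SGCE", "t", 1, k * g$samples, 2000)
    fk <- extract_features(reck)
    for (nm in c(feature_names(), "theta_elev", "gamma_elev"))
      expect_equal(fk[[nm]], f1[[nm]], tolerance = 1e-9)
  }
})

test_that("theta fraction increases with 6 Hz AM depth on matched seeds", {
  fr <- vapply(c(0, 0.2, 0.4, 0.8), function(m) {
    g <- generate_recording_signal(2000, 20, c(theta = m, alpha = 0,
                                               beta = 0, gamma = 0), seed = 7)
    rec <- mer_recording("p", "SGCE", "t", 1, g$samples, 2000)
    extract_features(rec)$theta_frac
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_equal(fr[1], 4 / 198, tolerance = 0.2)  # m = 0 ~ white baseline
})
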