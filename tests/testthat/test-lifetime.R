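test_that("reconvolution reduces to the pure decay for a delta IRF", {
  bins <- seq(0.008, by = 0.016, length.out = 500)
  irf <- c(1, rep(0, 499))
  m <- reconvolve(2.2, 1, irf, bins)
  t_rel <- (seq_along(bins) - 1) * 0.016
  expect_equal(m, exp(-t_rel / 2.2), tolerance = 1e-12)

  # splitting one amplitude across two identical lifetimes changes nothing
  m2 <- reconvolve(c(2.2, 2.2), c(0.5, 0.5), irf, bins)
  expect_equal(m2, m, tolerance = 1e-12)

  expect_error(reconvolve(-1, 1, irf, bins), "> 0")
})

test_that("a broadened IRF shifts the peak but preserves the scaled total", {
  bins <- tcspc_bins()
  irf <- gaussian_irf(bins, fwhm = 0.05, center = 0.5)
  m <- reconvolve(2.2, 1, irf, bins, total = 1e6)
  expect_equal(sum(m), 1e6, tolerance = 1e-9)
  expect_gt(bins[which.max(m)], 0.45)  # peak near the IRF position
  # cross-check against direct numerical convolution at a few bins
  irf_n <- irf / sum(irf)
  t_rel <- (seq_along(bins) - 1) * 0.016
  direct <- sapply(c(100, 500, 1200), function(j)
    sum(irf_n[1:j] * exp(-(t_rel[j] - t_rel[1:j]) / 2.2)))
  scale <- 1e6 / sum(stats::convolve(irf_n, rev(exp(-t_rel / 2.2)),
                                     type = "open")[seq_along(bins)])
  expect_equal(m[c(100, 500, 1200)], direct * scale, tolerance = 1e-8)
})

test_that("lifetimes are recovered from seeded synthetic decays", {
  pp <- decay_preset("free_dCPyTP")
  gm <- gen_decay(pp$lifetimes, pp$amplitudes, total_counts = 1e6, seed = 4)
  f1 <- fit_decay(gm$histogram, 1, seed = 4)
  expect_lt(rel_err(f1$lifetimes, 2.2), 0.02)
  # the measured (Poisson-noisy) IRF adds a little model error beyond pure
  # counting statistics, hence the slightly wider chi2 window here
  expect_gt(f1$chi2_reduced, 0.85)
  expect_lt(f1$chi2_reduced, 1.15)

  pb <- decay_preset("bound_dCPyTP")
  gb <- gen_decay(pb$lifetimes, pb$amplitudes, total_counts = 1e6, seed = 4)
  f2 <- fit_decay(gb$histogram, 2, seed = 4)
  expect_lt(rel_err(f2$lifetimes[1], 0.85), 0.05)
  expect_lt(rel_err(f2$lifetimes[2], 3.6), 0.05)
  expect_equal(sum(f2$amplitudes), 1)
})

test_that("recovery bias is below 1% at 1e6 counts across the lifetime range", {
  for (tau in c(0.5, 2.2, 5)) {
    g <- gen_decay(tau, 1, total_counts = 1e6, expected_only = TRUE)
    f <- fit_decay(g$histogram, 1, seed = 1)
    expect_lt(rel_err(f$lifetimes, tau), 0.01)
  }
})

test_that("overfitting a mono-exponential decay is detected as collapse", {
  g <- gen_decay(2.2, 1, total_counts = 1e6, seed = 8)
  expect_warning(f <- fit_decay(g$histogram, 2, seed = 8), "collapsed")
  expect_true(f$collapsed)
})

test_that("model selection picks the parsimonious adequate model", {
  g1 <- gen_decay(2.2, 1, total_counts = 1e6, seed = 12)
  expect_equal(select_model(g1$histogram, seed = 12), 1L)

  pb <- decay_preset("bound_dCPyTP")
  g2 <- gen_decay(pb$lifetimes, pb$amplitudes, total_counts = 1e6, seed = 12)
  expect_equal(select_model(g2$histogram, seed = 12), 2L)

  # information-poor histogram: parsimony default
  g3 <- gen_decay(pb$lifetimes, pb$amplitudes, total_counts = 200, seed = 12)
  expect_equal(select_model(g3$histogram, seed = 12), 1L)
})

test_that("chi2_reduced is calibrated against regenerated Poisson data", {
  # calibration of the statistic itself: exact IRF, and a 0-12 ns window so
  # every bin keeps an expected count well above 1 (the chi-square
  # approximation breaks on near-empty tail bins)
  pp <- decay_preset("free_dCPyTP")
  bins <- seq(0.008, by = 0.016, length.out = 750)
  chis <- vapply(1:8, function(s) {
    g <- gen_decay(pp$lifetimes, pp$amplitudes, total_counts = 1e6, seed = s,
                   bins = bins, noisy_irf = FALSE)
    fit_decay(g$histogram, 1, seed = s)$chi2_reduced
  }, 0)
  expect_true(all(chis > 0.9 & chis < 1.1))
})

test_that("degenerate histograms are rejected", {
  bins <- tcspc_bins()
  expect_error(decay_histogram(bins, rep(0, length(bins)),
                               rep(1, length(bins))), "total counts")
  expect_error(decay_histogram(bins[c(1, 3, 4)], 1:3, 1:3), "uniform")
})
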