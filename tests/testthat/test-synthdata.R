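test_that("generators are pure functions of their seed", {
  t1 <- gen_stopped_flow(small_scheme2_truth(noise_sigma = 0.01, seed = 33))
  t2 <- gen_stopped_flow(small_scheme2_truth(noise_sigma = 0.01, seed = 33))
  expect_identical(t1$traces, t2$traces)

  q1 <- gen_quench(preset_truth_quench(seed = 5))
  q2 <- gen_quench(preset_truth_quench(seed = 5))
  expect_identical(q1$courses, q2$courses)

  d1 <- gen_decay(2.2, 1, total_counts = 1e4, seed = 9)
  d2 <- gen_decay(2.2, 1, total_counts = 1e4, seed = 9)
  expect_identical(d1$histogram, d2$histogram)

  a1 <- gen_alignment(n_sequences = 25, seed = 13, ref_length = 470)
  a2 <- gen_alignment(n_sequences = 25, seed = 13, ref_length = 470)
  expect_identical(a1$alignment, a2$alignment)
})

test_that("noiseless stopped-flow traces equal the forward model", {
  truth <- small_scheme2_truth(noise_sigma = 0)
  gen <- gen_stopped_flow(truth)
  d <- truth$design[2, ]
  direct <- simulate_trace(truth$mechanism, truth$params, truth$observable,
                          initial_concentrations(truth$mechanism, d$enzyme,
                                                 d$primer, d$nucleotide),
                          times = truth$times, channel = "CPy")
  expect_equal(gen$traces[[2]]$signal, direct$signal, tolerance = 1e-12)
  # design metadata propagates to the trace
  expect_equal(gen$traces[[2]]$conc_enzyme, d$enzyme)
  expect_equal(length(gen$traces), nrow(truth$design))
})

test_that("quench generator respects the kinetics and the kpol = 0 limit", {
  truth <- preset_truth_quench(noise_sigma = 0)
  truth$params[["kpol"]] <- 0
  flat <- gen_quench(truth)
  for (tc in flat$courses) expect_equal(tc$product_fraction,
                                        rep(0, length(tc$times)))

  # rapid-equilibrium regime with trace primer: kobs follows the hyperbola
  truth2 <- preset_truth_quench(noise_sigma = 0)
  truth2$design$primer <- 0.05
  gen <- gen_quench(truth2)
  es <- equilibrium_summary(truth2$params)
  # only the final (conformationally adjusted) complex reacts, so the
  # apparent maximal rate is kpol * K2/(1+K2) on the Kd_total hyperbola
  kpol_app <- truth2$params[["kpol"]] * es$K2 / (1 + es$K2)
  for (tc in gen$courses) {
    kobs <- fit_product_exponential(tc)$kobs
    pred <- kobs_hyperbola(tc$conc_titrant, es$Kd_total, kpol_app)
    expect_lt(rel_err(kobs, pred), 0.05)
  }

  # binomial gel-depth noise stays within [0, 1]
  bn <- gen_quench(preset_truth_quench(seed = 3), noise_model = "binomial",
                   binomial_depth = 50)
  for (tc in bn$courses) {
    expect_true(all(tc$product_fraction >= 0 & tc$product_fraction <= 1))
    expect_true(all(tc$product_fraction * 50 ==
                      round(tc$product_fraction * 50)))
  }
})

test_that("decay generator matches its expected-value mode and presets", {
  g <- gen_decay(2.2, 1, total_counts = 5e5, expected_only = TRUE)
  m <- reconvolve(2.2, 1, gaussian_irf(tcspc_bins()), tcspc_bins(),
                  total = 5e5)
  expect_equal(g$histogram$counts, m, tolerance = 1e-12)

  pp <- decay_preset("free_dCPyTP")
  expect_equal(pp$lifetimes, 2.2)
  pb <- decay_preset("bound_dCPyTP")
  expect_equal(pb$lifetimes, c(0.85, 3.6))
  expect_equal(pb$amplitudes, c(0.5, 0.5))
})

test_that("largest-remainder allocation reproduces printed compositions", {
  counts <- allocate_counts(469, c(D = 0.723, E = 0.273, other = 0.004))
  expect_equal(unname(counts), c(339L, 128L, 2L))
  expect_equal(sum(counts), 469L)
  expect_equal(allocate_counts(10, c(A = 1)), c(A = 10L))
})

test_that("synthetic alignment columns carry the allocated composition exactly", {
  gen <- gen_alignment(n_sequences = 469, seed = 17)
  prof <- column_frequencies(gen$alignment, 395)
  expect_equal(prof$count[prof$residue == "D"], 339L)
  expect_equal(prof$count[prof$residue == "E"], 128L)
  expect_equal(sum(prof$count), 469L)
  expect_equal(prof$percent[prof$residue == "D"], 100 * 339 / 469)
  # strictly conserved pocket positions
  expect_equal(column_frequencies(gen$alignment, 404)$percent, 100)
  expect_equal(column_frequencies(gen$alignment, 449)$residue, "W")
  # reference carries the majority residue
  expect_equal(substr(gen$alignment$records[["human_TdT"]], 395, 395), "D")
})

test_that("generator-fitter recovery error shrinks with the noise level", {
  truth <- mutant_activity_truth()
  errs <- vapply(c(0.05, 0.01, 0), function(sg) {
    tr <- gen_multiexp_trace(truth$wt_kobs, truth$amplitudes, truth$offset,
                             noise_sigma = sg, seed = 7)
    fit <- fit_multiexponential(tr, 3, seed = 2)
    sum(rel_err(fit$kobs, truth$wt_kobs))
  }, 0)
  expect_lt(errs[3], 1e-6)
  expect_lt(errs[2], errs[1])
})
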