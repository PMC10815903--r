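test_that("simulated signal follows the response model in static limits", {
  m2 <- build_scheme("scheme2")
  p0 <- rate_parameters(k1 = 0, k_minus1 = 0, k2 = 0, k_minus2 = 0)
  times <- stopped_flow_times(50)

  obs <- observable_model(c(E = 1), F0 = 0, kbleach = 0)
  tr <- simulate_trace(m2, p0, obs, c(E = 1, N = 0), times, channel = "CPy")
  expect_equal(tr$signal, rep(1, 50), tolerance = 1e-10)

  # static chemistry + bleaching: pure mono-exponential decay to F0
  obs_b <- observable_model(c(E = 2), F0 = 0.5, kbleach = 0.3)
  tr_b <- simulate_trace(m2, p0, obs_b, c(E = 1, N = 0), times)
  expect_equal(tr_b$signal, (2 + 0.5 - 0.5) * exp(-0.3 * times) + 0.5,
               tolerance = 1e-10)

  expect_error(simulate_trace(m2, p0, obs, c(E = -1, N = 0), times), ">= 0")
})

test_that("photobleach correction inverts the forward bleach model", {
  truth <- preset_truth("trp_scheme1", noise_sigma = 0, seed = 1)
  truth$design <- truth$design[3, , drop = FALSE]
  truth$times <- stopped_flow_times(120)
  bleached <- gen_stopped_flow(truth)$traces[[1]]
  expect_equal(bleached$kbleach, 0.08)

  ideal_truth <- truth
  ideal_truth$observable$kbleach <- 0
  ideal <- gen_stopped_flow(ideal_truth)$traces[[1]]

  corrected <- correct_photobleach(bleached)
  expect_lt(max(abs(corrected$signal - ideal$signal)), 1e-10)

  # kbleach = 0 and flat-at-background traces are fixed points
  flat <- kin_trace(ideal$times, rep(0.2, 120), "Trp", F0 = 0.2, kbleach = 0.4)
  expect_equal(correct_photobleach(flat)$signal, rep(0.2, 120))
  expect_equal(correct_photobleach(ideal, kbleach = 0)$signal, ideal$signal)
})

test_that("kbleach is recovered from calibration traces", {
  t <- seq(0.01, 30, length.out = 200)
  clean <- kin_trace(t, 0.4 + 1.3 * exp(-0.05 * t), "Trp")
  est <- estimate_kbleach(clean)
  expect_equal(est$kbleach, 0.05, tolerance = 1e-6)
  expect_equal(est$F0, 0.4, tolerance = 1e-4)

  expect_warning(est0 <- estimate_kbleach(kin_trace(t, rep(1, 200), "Trp")),
                 "does not decay")
  expect_equal(est0$kbleach, 0)

  set.seed(3)
  noisy <- kin_trace(t, 0.4 + 1.3 * exp(-0.05 * t) +
                       rnorm(200, sd = 0.013), "Trp")
  expect_lt(rel_err(estimate_kbleach(noisy)$kbleach, 0.05), 0.05)
})

test_that("pseudo-first-order relaxation of two-state binding is reproduced", {
  # k2 = 0 reduces scheme 2 to E + N <=> X1 with rate k1*[N] + k_minus1
  m2 <- build_scheme("scheme2")
  p <- rate_parameters(k1 = 2, k_minus1 = 40, k2 = 0, k_minus2 = 1)
  obs <- observable_model(c(X1 = 5), F0 = 0.1)
  times <- stopped_flow_times(200, t_max = 0.2)
  tr <- simulate_trace(m2, p, obs, c(E = 0.05, N = 50), times, channel = "CPy")
  fit <- fit_multiexponential(tr, 1)
  expect_lt(rel_err(fit$kobs, 2 * 50 + 40), 0.01)
})

test_that("multi-exponential fits recover phases and flag degeneracy", {
  t <- stopped_flow_times(300)
  one <- kin_trace(t, 2 - 0.8 * exp(-3 * t), "CPy")
  f1 <- fit_multiexponential(one, 1)
  expect_equal(f1$kobs, 3, tolerance = 1e-6)
  expect_equal(f1$amplitudes, -0.8, tolerance = 1e-6)
  expect_equal(f1$offset, 2, tolerance = 1e-6)

  set.seed(9)
  truth_k <- c(80, 4, 0.4)
  amps <- c(-0.5, -1, 0.8)
  sig <- 2 + as.numeric(exp(-outer(t, truth_k)) %*% amps)
  noisy <- kin_trace(t, sig + rnorm(length(t), sd = 0.01 * diff(range(sig))),
                     "CPy")
  f3 <- fit_multiexponential(noisy, 3, seed = 2)
  expect_lt(max(rel_err(f3$kobs, truth_k)), 0.05)

  flat <- kin_trace(t, rep(1.5, length(t)), "CPy")
  ff <- fit_multiexponential(flat, 1)
  expect_lt(abs(ff$amplitudes), 1e-8)

  expect_error(fit_multiexponential(kin_trace(1:5, 1:5, "CPy"), 3),
               "too few points")
})

test_that("relative activity ratios match phase order and reject mismatch", {
  t <- stopped_flow_times(300)
  mk <- function(k) {
    sig <- 2 + as.numeric(exp(-outer(t, k)) %*% c(-0.5, -1, 0.8))
    fit_multiexponential(kin_trace(t, sig, "CPy"), 3)
  }
  wt <- mk(c(80, 4, 0.4))
  expect_equal(relative_activity(wt, wt), c(1, 1, 1), tolerance = 1e-6)
  mut <- mk(c(80, 4, 0.8))
  expect_equal(relative_activity(mut, wt), c(1, 1, 2), tolerance = 1e-4)
  one <- fit_multiexponential(kin_trace(t, 2 - exp(-3 * t), "CPy"), 1)
  expect_error(relative_activity(one, wt), "mismatch")
})

test_that("global fit recovers scheme-2 constants from a noise-free series", {
  truth <- small_scheme2_truth()
  gen <- gen_stopped_flow(truth)
  b <- scheme2_bounds()
  fit <- fit_global(gen$traces, truth$mechanism,
                    free = c("k1", "k_minus1", "k2", "k_minus2"),
                    lower = b$lower, upper = b$upper,
                    specs = preset_response_spec("cpy_scheme2"),
                    n_starts = 12, n_refine = 4, n_hops = 1, seed = 11)
  expect_true(fit$converged)
  for (nm in c("k1", "k_minus1", "k2", "k_minus2"))
    expect_lt(rel_err(fit$parameters[[nm]], truth$params[[nm]]), 1e-3)
  # fitted responses are unique under the fixed-normalization convention
  expect_equal(unname(fit$responses$CPy$coef["X1"]), 3.5, tolerance = 1e-3)
  expect_equal(unname(fit$responses$CPy$coef["X2"]), 6.0, tolerance = 1e-3)
  expect_equal(fit$responses$CPy$F0, 0.2, tolerance = 1e-3)
})

test_that("zero-signal traces are flagged non-identifiable", {
  t <- stopped_flow_times(50)
  dead <- list(kin_trace(t, rep(0, 50), "CPy", 1, 0, 3),
               kin_trace(t, rep(0, 50), "CPy", 2, 0, 3))
  b <- scheme2_bounds()
  expect_warning(
    fit <- fit_global(dead, build_scheme("scheme2"),
                      free = c("k1", "k_minus1", "k2", "k_minus2"),
                      lower = b$lower, upper = b$upper,
                      specs = preset_response_spec("cpy_scheme2")),
    "non-identifiable")
  expect_false(fit$converged)
  expect_true("non_identifiable" %in% fit$flags)
})
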