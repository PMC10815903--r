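test_that("product-accumulation exponential fit recovers kobs", {
  t <- quench_times()
  clean <- product_time_course(t, 0.9 * (1 - exp(-0.5 * t)), conc_titrant = 5)
  pt <- fit_product_exponential(clean)
  expect_equal(pt$kobs, 0.5, tolerance = 1e-8)
  expect_equal(pt$A, 0.9, tolerance = 1e-8)

  expect_error(fit_product_exponential(
    product_time_course(t, rep(0, length(t)))), "does not increase")
  expect_error(fit_product_exponential(product_time_course(1:3, c(0, .1, .2))),
               "at least 4")

  set.seed(5)
  t10 <- seq(0.2, 12, length.out = 10)
  noisy <- product_time_course(
    t10, pmax(0.9 * (1 - exp(-0.5 * t10)) + rnorm(10, sd = 0.02), 0), 5)
  expect_lt(rel_err(fit_product_exponential(noisy)$kobs, 0.5), 0.1)
})

test_that("hyperbolic fit recovers Kd and kpol and obeys the half-saturation identity", {
  conc <- c(1, 2, 5, 10, 20)
  pts <- lapply(conc, function(c0)
    structure(list(conc = c0, kobs = kobs_hyperbola(c0, Kd = 5, kpol = 2),
                   kobs_stderr = 0), class = "kobs_point"))
  hyp <- fit_kobs_hyperbola(pts)
  expect_equal(hyp$Kd, 5, tolerance = 1e-7)
  expect_equal(hyp$kpol, 2, tolerance = 1e-7)
  expect_equal(hyp$K_assoc, 1 / hyp$Kd)
  # at c = Kd the fitted curve sits at half the maximal rate
  expect_equal(kobs_hyperbola(hyp$Kd, hyp$Kd, hyp$kpol), hyp$kpol / 2)
  # printed association form is the same curve
  expect_equal(kobs_hyperbola_assoc(conc, 1 / 5, 2),
               kobs_hyperbola(conc, 5, 2))

  # monotone increasing in c, bounded above by kpol
  cc <- seq(0.1, 100, length.out = 50)
  curve <- kobs_hyperbola(cc, hyp$Kd, hyp$kpol)
  expect_true(all(diff(curve) > 0))
  expect_true(all(curve < hyp$kpol))
})

test_that("saturated and linear-regime titrations are flagged", {
  sat <- lapply(c(50, 100, 200, 400), function(c0)
    structure(list(conc = c0, kobs = kobs_hyperbola(c0, 0.5, 2)),
              class = "kobs_point"))
  expect_true("saturated_Kd_unidentifiable" %in% fit_kobs_hyperbola(sat)$flags)

  lin <- lapply(c(0.1, 0.2, 0.4, 0.8), function(c0)
    structure(list(conc = c0, kobs = kobs_hyperbola(c0, 500, 2)),
              class = "kobs_point"))
  expect_true(any(grepl("lower_bound", fit_kobs_hyperbola(lin)$flags)))

  expect_error(fit_kobs_hyperbola(sat[1:2]), ">= 3")
})

test_that("quench pipeline Kd agrees with the mechanism's overall Kd", {
  # rapid-equilibrium scheme-1 conditions with trace primer (no nucleotide
  # depletion): hyperbola Kd ~ Kd_total of the two-step binding
  truth <- preset_truth_quench(noise_sigma = 0)
  truth$design$primer <- 0.05
  gen <- gen_quench(truth, times = exp(seq(log(0.05), log(30), length.out = 10)))
  pts <- lapply(gen$courses, fit_product_exponential)
  hyp <- fit_kobs_hyperbola(pts)
  es <- equilibrium_summary(truth$params)
  expect_lt(rel_err(hyp$Kd, es$Kd_total), 0.15)
  kpol_app <- truth$params[["kpol"]] * es$K2 / (1 + es$K2)
  expect_lt(rel_err(hyp$kpol, kpol_app), 0.15)
})
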