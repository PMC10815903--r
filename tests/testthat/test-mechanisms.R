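test_that("built-in schemes have the expected topology", {
  m2 <- build_scheme("scheme2")
  expect_equal(nrow(m2$species), 4L)
  expect_length(m2$reactions, 2L)
  expect_true(all(!vapply(m2$reactions, function(r) is.na(r$rate_rev), NA)))

  m1 <- build_scheme("scheme1")
  irrev <- vapply(m1$reactions, function(r) is.na(r$rate_rev), NA)
  expect_equal(sum(irrev), 1L)  # only the chemistry step is irreversible
  expect_equal(m1$reactions[[which(irrev)]]$rate_fwd, "kpol")

  # without the second cycle the extended-primer complex is terminal
  m3 <- build_scheme("scheme3", second_cycle = FALSE)
  reactants <- unlist(lapply(m3$reactions, `[[`, "reactants"))
  expect_false("ED1" %in% reactants)
  expect_true("ED1" %in% m3$species$name)

  # binding-only sub-model for slowly incorporated ddATP
  mb <- build_scheme("scheme1", binding_only = TRUE)
  expect_equal(sort(mb$species$name), sort(c("ED", "N", "C1", "C2")))
  expect_length(mb$reactions, 2L)

  expect_error(build_scheme("scheme9"), "valid schemes.*scheme1")
})

test_that("mass-action right-hand side reproduces hand-computed fluxes", {
  m2 <- build_scheme("scheme2")
  p0 <- rate_parameters(k1 = 0, k_minus1 = 0, k2 = 0, k_minus2 = 0)
  rhs0 <- derive_rhs(m2, p0)
  y <- c(E = 1, N = 2, X1 = 0.5, X2 = 0.1)
  expect_equal(rhs0(0, y, NULL)[[1]], rep(0, 4))

  p1 <- rate_parameters(k1 = 1, k_minus1 = 0, k2 = 0, k_minus2 = 0)
  d <- derive_rhs(m2, p1)(0, c(E = 1, N = 1, X1 = 0, X2 = 0), NULL)[[1]]
  expect_equal(d, c(-1, -1, 1, 0))  # single bimolecular flux of 1 uM/s

  expect_error(derive_rhs(m2, c(k1 = 1)), "k_minus1")
})

test_that("conserved moieties annihilate the RHS for all schemes", {
  set.seed(42)
  for (nm in c("scheme1", "scheme2", "scheme3")) {
    m <- build_scheme(nm)
    mo <- conserved_moieties(m)
    for (rep in 1:100) {
      p <- random_rates(m)
      rhs <- derive_rhs(m, p)
      y <- random_state(m)
      dy <- rhs(0, y, NULL)[[1]]
      for (w in mo)
        expect_lt(abs(sum(w * dy[match(names(w), m$species$name)])), 1e-12)
    }
  }
})

test_that("moiety weights count incorporated nucleotides", {
  m2 <- build_scheme("scheme2")
  expect_equal(conserved_moieties(m2)$enzyme, c(E = 1, X1 = 1, X2 = 1))
  expect_null(conserved_moieties(m2)$primer)
  m3 <- build_scheme("scheme3")
  nuc <- conserved_moieties(m3)$nucleotide
  expect_equal(unname(nuc[c("ED1", "ED2")]), c(1, 2))
})

test_that("scheme 2 has no incorporation species", {
  m2 <- build_scheme("scheme2")
  expect_true(all(tdtkinetics:::species_incorporated(m2) == 0))
})

test_that("equilibrium summary matches closed forms and the Kd convention flag", {
  p <- rate_parameters(k1 = 1, k_minus1 = 1, k2 = 1, k_minus2 = 1)
  es <- equilibrium_summary(p)
  expect_equal(es$K1, 1)
  expect_equal(es$K2, 1)
  expect_equal(es$Kd_total, 0.5)
  expect_equal(equilibrium_summary(p, convention = "final")$Kd_total, 1)

  p0 <- rate_parameters(k1 = 2, k_minus1 = 1, k2 = 0, k_minus2 = 1)
  expect_equal(equilibrium_summary(p0)$Kd_total, 0.5)  # one-step limit 1/K1

  pz <- rate_parameters(k1 = 1, k_minus1 = 0, k2 = 1, k_minus2 = 1)
  expect_error(equilibrium_summary(pz), "undefined equilibrium")
})

test_that("Kd_total predicts the ODE steady state of two-step binding", {
  set.seed(7)
  m2 <- build_scheme("scheme2")
  for (rep in 1:20) {
    p <- random_rates(m2)
    es <- equilibrium_summary(p)
    Et <- runif(1, 0.5, 3); Nt <- runif(1, 0.5, 5)
    t_end <- 200 / min(p)
    conc <- tdtkinetics:::solve_concentrations(
      m2, p, c(E = Et, N = Nt, X1 = 0, X2 = 0), c(t_end / 2, t_end))
    bound <- conc[2, "X1"] + conc[2, "X2"]
    K <- 1 / es$Kd_total
    pred <- uniroot(function(B) (Et - B) * (Nt - B) * K - B,
                    c(0, min(Et, Nt)), tol = 1e-12)$root
    expect_lt(abs(bound - pred) / pred, 1e-3)
  }
})

test_that("mechanism config round-trips losslessly", {
  for (m in list(build_scheme("scheme1", second_cycle_two_step = TRUE),
                 build_scheme("scheme2"),
                 build_scheme("scheme3", independent_cycle2 = TRUE))) {
    m2 <- mech_from_config(mech_to_config(m))
    expect_equal(m2, m)
  }
  custom <- mechanism(
    "mini",
    rbind(species("A", "enzyme", n_enzyme = 1),
          species("B", "complex", n_enzyme = 1)),
    list(reaction("A", "B", "kf", "kr")))
  rt <- mech_from_config(mech_to_config(custom))
  expect_equal(rt$species$name, custom$species$name)
  expect_equal(rt$reactions, custom$reactions)
})

test_that("invalid mechanisms are rejected", {
  expect_error(mechanism("bad",
                         rbind(species("A", "enzyme", n_enzyme = 1),
                               species("A", "enzyme", n_enzyme = 1)),
                         list()),
               "unique")
  expect_error(mechanism("bad", species("A", "enzyme", n_enzyme = 1),
                         list(reaction("A", "Z", "k"))),
               "undeclared")
  # a reaction destroying the enzyme moiety is caught at construction
  expect_error(mechanism("bad",
                         rbind(species("A", "enzyme", n_enzyme = 1),
                               species("B", "nucleotide", n_nucleotide = 1)),
                         list(reaction("A", "B", "k"))),
               "conserve")
  expect_error(rate_parameters(k1 = -1, k_minus1 = 1, k2 = 1, k_minus2 = 1),
               ">= 0")
})
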