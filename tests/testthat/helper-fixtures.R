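# Shared fixtures: small designs keep the ODE fits fast while preserving the
# identifiability structure of the full experimental designs.

# random positive rate set for a mechanism (log-uniform in [0.1, 10])
random_rates <- function(m) {
  nm <- required_rates(m)
  structure(setNames(10^runif(length(nm), -1, 1), nm),
            class = "rate_parameters")
}

# random positive state over the species of a mechanism
random_state <- function(m) setNames(runif(nrow(m$species), 0, 5),
                                     m$species$name)

# scheme-2 truth with a reduced design (3 enzyme concentrations, short grid)
small_scheme2_truth <- function(noise_sigma = 0, seed = 1, n_times = 150) {
  truth <- preset_truth("cpy_scheme2", noise_sigma = noise_sigma, seed = seed)
  truth$design <- truth$design[c(1, 3, 5), ]
  truth$times <- stopped_flow_times(n_times)
  truth
}

scheme2_bounds <- function() {
  list(lower = c(k1 = 0.1, k_minus1 = 0.05, k2 = 0.005, k_minus2 = 5e-4),
       upper = c(k1 = 3000, k_minus1 = 1500, k2 = 160, k_minus2 = 10))
}

scheme3_bounds <- function() {
  list(lower = c(k1 = 0.3, k_minus1 = 0.05, k2 = 0.042, k_minus2 = 0.016,
                 kpol = 0.01, kt = 0.005),
       upper = c(k1 = 3000, k_minus1 = 500, k2 = 420, k_minus2 = 160,
                 kpol = 100, kt = 50))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
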