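# tdtkinetics

Transient-kinetic analysis of template-independent DNA polymerisation by
human terminal deoxynucleotidyl transferase (TdT), the enzyme that adds
untemplated nucleotides to 3' DNA ends during V(D)J recombination. The
package is aimed at enzymologists analysing pre-steady-state data: it turns
stopped-flow fluorescence series, quench-flow product time courses and
photon-counting lifetime decays into elementary rate constants, and profiles
the conservation of the dNTP-binding pocket across a protein family
alignment.

## What it computes

**Mechanistic models.** Nucleotide binding is two-staged — an encounter
complex followed by a conformational adjustment of the enzyme to the incoming
base — optionally followed by irreversible incorporation and a post-catalytic
complex transformation:

    E·D + N  ⇌(k1/k−1)  C1  ⇌(k2/k−2)  C2  →(kpol)  P*  →(kt)  E·D1  (+ second cycle)

`build_scheme()` declares the three built-in variants (binding-only without
primer; binding + one irreversible incorporation for chain-terminating ddNTPs;
the full multi-turnover cycle), `derive_rhs()` compiles them to mass-action
ODEs with analytically conserved enzyme/primer/nucleotide moieties, and
`equilibrium_summary()` reports K1 = k1/k−1, K2 = k2/k−2 and the overall
dissociation constant Kd = 1/(K1·(1+K2)).

**Global fitting.** `fit_global()` fits rate constants to whole
concentration series at once: fluorescence responses and backgrounds are
profiled out linearly at every step (variable projection), rates are searched
in log space by a seeded, screened multi-start Levenberg–Marquardt with
symmetry restarts and valley descent, photobleaching is corrected via
F = (F_obs − F0)·e^(k_bleach·t) + F0 with per-concentration calibrated rates,
and everything before the 1.38 ms instrument dead time is ignored.

**Quench-flow.** `fit_product_exponential()` extracts kobs from
P(t) = A·(1 − e^(−kobs·t)); `fit_kobs_hyperbola()` fits
kobs = kpol·[S]/(Kd + [S]) to the titration, flagging saturated or
curvature-free designs.

**Lifetimes.** `fit_decay()` fits TCSPC histograms by IRF reconvolution with
Poisson-weighted chi-square; `select_model()` chooses between one and two
exponential components by F-test with collapse guards.

**Conservation.** `filter_redundancy()`, `map_reference_position()`,
`column_frequencies()` and `pocket_profile()` turn an aligned FASTA into
per-position residue percentage tables in human-TdT numbering (positions
395, 397, 404, 449, 453, 456, 457 by default).

**Synthetic data.** The study's raw traces are available only on request, so
`gen_stopped_flow()`, `gen_quench()`, `gen_decay()` and `gen_alignment()`
generate every input from seeded ground truths that emulate the published
experimental designs (`preset_truth()`, `decay_preset()`,
`table_compositions()`).

## Worked example

Fit the primer-free fluorescent-nucleotide titration (five enzyme
concentrations, 1% noise averaged over five replicates) and recover the
two-stage binding constants:

```r
library(tdtkinetics)

truth <- preset_truth("cpy_scheme2", seed = 1)   # k2 truth: 1.6 s^-1
series <- gen_stopped_flow(truth)
fit <- fit_global(series$traces, truth$mechanism,
                  free  = c("k1", "k_minus1", "k2", "k_minus2"),
                  lower = c(k1 = 0.1, k_minus1 = 0.05, k2 = 0.005, k_minus2 = 5e-4),
                  upper = c(k1 = 3000, k_minus1 = 1500, k2 = 160, k_minus2 = 10),
                  specs = preset_response_spec("cpy_scheme2"),
                  n_starts = 20, n_refine = 6, n_hops = 2, seed = 1)
fit
#> <global_fit> RSS = 3.15174 (converged)
#>   k1         29.7617  (se 0.195)
#>   k_minus1   89.71  (se 0.621)
#>   k2         1.60426  (se 0.0125)
#>   k_minus2   0.0627926  (se 0.00123)
```

The fitted `k2` (the forward rate of the conformational second binding
stage) lands on the generating value 1.6 s⁻¹ to 0.3%; the standard errors
come from the log-space Gauss–Newton covariance. The same call with
`"cpy_scheme3"` (primer present, six free constants including `kpol` and the
post-catalytic `kt`) recovers its k2 = 4.2 s⁻¹ within a few percent.

A lifetime run is a one-liner per sample:

```r
pp <- decay_preset("bound_dCPyTP")               # 0.85 / 3.6 ns, equal weights
h  <- gen_decay(pp$lifetimes, pp$amplitudes, total_counts = 1e6, seed = 1)
fit_decay(h$histogram, select_model(h$histogram, seed = 1), seed = 1)
#> <lifetime_fit> 2 component(s), chi2_red = 1.169
#>   tau = 0.8248 ns (fraction 0.490)
#>   tau = 3.55 ns (fraction 0.510)
```

The numbered scripts under `analysis/` run the whole study in order —
simulation, transient global fits, quench Kd/kpol, lifetimes, conservation
profiling, mutant relative activity — writing tables under `results/`.

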