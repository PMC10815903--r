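---
title: "Models and methods: transient kinetics of template-independent DNA polymerisation"
author: "tdtkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdtkinetics)
```

## The system and the models

Terminal deoxynucleotidyl transferase (TdT) extends single-stranded DNA 3'
ends without a template, the activity that inserts untemplated nucleotides
during V(D)J recombination. Pre-steady-state experiments resolve the first
turnover of the enzyme into elementary steps: stopped-flow fluorescence
(intrinsic tryptophan, or a pyrrolocytosine nucleotide analogue, "CPy")
watches conformational events in real time from about a millisecond after
mixing, while rapid chemical quench (quench-flow) measures product formation
directly. This package implements the full analysis chain for such data, with
seeded synthetic generators standing in for the instrument files.

Three mass-action schemes describe the observations (`build_scheme()`):

* **Scheme 1** (Trp channel, dideoxy-NTP with primer): the preformed
  enzyme–primer complex binds the nucleotide in two reversible stages — an
  initial encounter complex and a conformational adjustment of the enzyme to
  the incoming base — followed by irreversible incorporation (`kpol`). The
  dideoxy-terminated product can only re-bind a second nucleotide, so the
  second cycle is binding-only.
* **Scheme 2** (CPy channel, no primer): free enzyme binds the fluorescent
  nucleotide in the same two reversible stages; no chemistry occurs.
* **Scheme 3** (CPy channel, with primer): two-stage binding, incorporation,
  then a first-order transformation of the post-catalytic complex (`kt`)
  yielding the extended-primer complex, which runs an identical second
  binding/catalysis cycle (multi-turnover of the fluorescent nucleotide).

Units are fixed at µM and seconds; bimolecular constants are µM⁻¹s⁻¹, which
keeps every quantity near unity at the experimental concentrations. Each
species carries an enzyme/primer/nucleotide composition, so every reaction is
checked for moiety conservation at construction time and
`conserved_moieties()` returns weight vectors that annihilate the mass-action
right-hand side analytically — a property the test suite verifies to 1e-12,
independent of any solver. The two-stage binding summarises to `K1 = k1/k−1`
(µM⁻¹), `K2 = k2/k−2`, and an overall dissociation constant. The package
default is the thermodynamically exact two-step form
`Kd = 1/(K1·(1+K2))`, counting both bound states as bound; the alternative
convention `1/(K1·K2)` (only the final complex counts) is available via
`equilibrium_summary(..., convention = "final")`, since the choice cannot be
settled from the stated definitions alone.

## The fluorescence observable and photobleaching

The ideal signal is linear in the species concentrations,
`F_ideal(t) = F0 + Σ r_i c_i(t)`, with response coefficients `r_i` in
a.u./µM. Continuous irradiation bleaches the fluorophores; the observed
signal is modelled as exponential attenuation of the above-background
component,

`F_obs(t) = (F_ideal(t) − F0)·exp(−k_bleach·t) + F0`,

and `correct_photobleach()` applies the exact inverse. The bleach rate is
estimated per concentration from chemically static calibration traces
(`estimate_kbleach()`) and held fixed during fitting; co-fitting a shared
bleach rate is an opt-in flag (`co_fit_kbleach`). Traces start at the
instrument dead time (1.38 ms) and fits ignore anything earlier; the default
grid is 400 logarithmic points from the dead time to 10 s, the window beyond
which bleaching swamps the signal.

Because fluorescence is in arbitrary units, the response scale must be fixed
by convention: one coefficient per channel is held at a known value (free
nucleotide for the CPy channel, the unbound enzyme–primer complex for the Trp
channel). The remaining responses are constrained by *fluorophore
additivity*: a species carrying an incorporated dye and a newly bound one
responds with the sum of the corresponding environment responses
(`response_spec()` accepts tied response groups). This both mirrors the
physics and keeps the linear subproblem well conditioned when a titration
probes few distinct initial states.

## Global fitting

`fit_global()` minimises the summed squared residuals over all traces of a
concentration series simultaneously. Two structural choices matter:

* **Variable projection.** For any candidate set of rate constants the free
  responses and background enter the model linearly, so they are profiled out
  exactly by linear least squares at every step. Only the rate constants are
  searched nonlinearly (in log space), which removes most of the
  dimensionality and all of the response/rate scaling interplay.
* **Structured multi-start.** The objective is nonconvex with long, curved,
  nearly flat valleys along correlated rate combinations. The search uses
  stratified (Latin-hypercube) log-uniform draws within the bounds, screens
  them by a short Levenberg–Marquardt polish (raw residuals barely separate
  basins), refines the best few fully, then runs exchange-symmetry restarts
  (sequential first-order steps can trade roles between local optima),
  multiplicative profile restarts of each slow-step rate, and a valley-descent
  loop alternating deep polishes with small log-space jitters. Everything is
  deterministic given the seed.

One numerical detail proved decisive: the finite-difference step used for the
Jacobian must sit well above the ODE solver noise. With the default
square-root-of-machine-epsilon step, derivative estimates are dominated by
integrator error (relative tolerance 1e-8) and the optimiser stalls far from
the optimum; the package sets the step so that parameter perturbations are
~1e-3 in log-space, after which noise-free series are recovered to machine-
level residuals. Solver tolerances are rtol 1e-8 / atol 1e-10 throughout, and
mass-action derivatives are evaluated in compiled code.

Fits report per-parameter standard errors (delta method on the log-space
Gauss–Newton covariance), the residual sum of squares, convergence and
degeneracy flags (all-zero traces are flagged non-identifiable rather than
fitted), and the profiled responses. Residual weighting is unweighted by
default, with per-trace inverse-variance weighting as an option. The
dideoxy-ATP special case — too slow for its chemistry to register before
photobleaching — is handled by the `binding_only` scheme-1 variant fitted to
traces truncated at 2 s, with its incorporation rate taken from the
quench-flow module instead.

## Quench-flow analysis

Product accumulation in a single-turnover quench experiment follows
`P(t) = A·(1 − e^(−kobs·t))` (`fit_product_exponential()`; the amplitude is
fitted, since nothing states it was fixed). The concentration dependence of
`kobs` is hyperbolic; the package fits the standard dissociation form
`kobs = kpol·c/(Kd + c)` (`fit_kobs_hyperbola()`). The printed form of this
relation uses an association-type constant `K` (µM⁻¹); it is algebraically
identical with `Kd = 1/K`, and both parameterisations are exposed
(`kobs_hyperbola_assoc()`), so reports remain round-trippable while the
conventional units are primary. Saturated titrations (`Kd` far below the
sampled range) and linear-regime titrations (`Kd` far above it) are flagged
rather than reported as trustworthy numbers. On synthetic data generated from
the full scheme-1 simulation in the rapid-equilibrium limit (trace primer, so
the nucleotide is not depleted), the fitted `Kd` agrees with the mechanism's
overall two-step `Kd` to within the tolerance the test suite asserts (15%).
Because only the final, conformationally adjusted complex reacts, the fitted
maximal rate is the apparent `kpol·K2/(1+K2)`, not the elementary `kpol` — the
classic occupancy correction of two-step binding. The identity
`kobs(Kd) = kpol/2` is exact for the fitted curve.

## Fluorescence lifetime analysis

Time-correlated single-photon-counting decays are fitted by iterative
reconvolution: the measured instrument response (IRF) is convolved with a one-
or two-exponential decay, shifted by a fitted time-origin nuisance parameter,
scaled to the total observed counts, and compared with the counts by a
Poisson-weighted chi-square with `max(count, 1)` variances (the standard
treatment of empty bins). Default bins are 16 ps over 0–25 ns; the synthetic
IRF is Gaussian with 0.05 ns FWHM, consistent with a picosecond excitation
pulse, and the generator draws the "measured" IRF with Poisson noise as a real
scatter measurement would. Lifetimes are searched in log space from seeded
multi-starts; amplitudes are reported as fractions summing to one, sorted by
lifetime. A two-component fit whose lifetimes collapse (ratio < 1.2) or whose
minor fraction vanishes (< 1%) is flagged; `select_model()` accepts the
second component only on an F-test at α = 0.01 and no collapse, so
information-poor histograms default to the parsimonious model. Fitting the
expected-value (infinite-count) histogram recovers the generating lifetimes
exactly; at finite counts the Neyman weighting biases the short lifetime of a
close pair slightly low (a few percent at 10⁶ counts), a known property of
this weighting that stays well inside the asserted tolerances.

## Conservation profiling

The alignment module consumes an aligned FASTA (alignment computation is
upstream), removes exact duplicates and fragments shorter than 80% of the
reference's ungapped length (true isoform detection needs database metadata
and is deliberately not attempted), maps reference-numbered residue positions
(1-based on the ungapped human sequence, the field's "Asp395" style) through
gaps, and tabulates per-column residue percentages over non-gap characters
with gaps counted separately. Ambiguity characters count in the denominator
by default; a flag excludes them. Profiles are invariant to record order and
to all-gap column insertion, and the redundancy filter is idempotent — all
property-tested.

## Synthetic data: what it emulates, and what it does not

No raw instrument data are distributed with the study, so seeded generators
reproduce the stated experimental designs: the Trp series (2 µM enzyme, 1 µM
primer, five dideoxy-NTP concentrations spanning 1–10 µM, with
photobleaching), the CPy series (1 µM primer, 3 µM fluorescent nucleotide,
five enzyme concentrations spanning 0.5–5 µM), the quench titration (2 µM
enzyme, 1 µM primer, 2–10 µM dNTP, eight time points 0.05–30 s), million-count
TCSPC histograms, and a 469-sequence alignment whose pocket columns follow the
reported frequencies by largest-remainder allocation (so recovered
percentages equal the generated composition exactly). Noise models: additive
Gaussian at 1% of trace span per individual stopped-flow experiment, with each
recorded curve the average of five independent experiments as in the stated
practice; Gaussian (default 2%) or binomial gel-depth noise on product
fractions; Poisson counting noise on photons. Generators are pure functions
of their seed.

Only a handful of generating constants are printed in the study: the
conformational-stage rates (1.6 s⁻¹ without primer, 4.2 s⁻¹ with), the
lifetimes (2.2 ns free; 0.85 and 3.6 ns bound), the mutant phase factors
(~4, ~13, ~16), and the pocket compositions. All other truth values are
package choices. They were fixed by two requirements: consistency with the
qualitative statements about the system (the primer stabilises the initial
complex roughly three-fold through the reverse rate; both second-stage rates
rise with primer while their ratio drops about six-fold; the overall
dissociation constant is similar with and without primer; incorporation is
fast for this analogue), and *identifiability* — a Fisher-information
analysis of the design, run before freezing the defaults, showed that a
saturating first binding step (`K1·[N] ≫ 1`) or overlapping slow phases make
the stage rates ill-determined from this design at the study noise. Since
the study's analysis did extract per-stage constants from such data, the
synthetic conditions must be ones under which that is possible; the defaults
are therefore `k1 = 30`,
`k−1 = 30`, `k2 = 4.2`, `k−2 = 1.0`, `kpol = 1.0`, `kt = 0.15` (scheme 3) and
`k1 = 30`, `k−1 = 90`, `k2 = 1.6`, `k−2 = 0.064` (scheme 2), with environment
responses 1 (free dye), 3.5 (loosely bound), 6.0 (tightly bound), 1.8
(post-chemistry complex) and 1.2 per incorporated residue, and enzyme levels
{0.5, 0.75, 1, 2.5, 5} µM. The schemes contain no free-enzyme species, so the
enzyme–primer complex is `min(enzyme, primer)` and titration above the primer
concentration adds no information — hence the extra sub-µM levels. The bound
lifetime pair uses equal amplitudes, a convention, not a claim about the real
sample; likewise the remainder bucket at position 395 is drawn from the rare
residues (K, N) without asserting their true frequencies.

What passing tests therefore show is that the pipeline — simulation,
correction, global fitting, model selection, profiling — is internally
correct and recovers known truths under realistic designs and noise. What
they cannot show is anything about instrument artifacts absent from the
generators (mixing transients, inner-filter effects, detector afterpulsing,
gel quantification error structure), nor that the real enzyme's constants
equal the synthetic defaults.

## Problem sizes and reproducibility

The shipped analyses and tests use the full five-trace designs at 400 time
points for the headline fits, and reduced three-trace/150-point versions of
the same designs for the noise-free recovery checks; TCSPC fits use the full
1562-bin histograms. Multi-start budgets are 12–24 starts with 4–8 refined,
which the recovery tests show is sufficient once the screening and descent
stages are in place. Every stochastic step — generators, start draws,
jitters — is driven by explicit integer seeds, and `run_*()` workflow
commands log the seed, solver tolerances and package version with each
report, so any report can be regenerated from its config.

## Known limitations

Enzyme titration above the primer concentration is uninformative under these
schemes (no free-enzyme binding pathway is modelled); responses are assumed
shared across a concentration series; the multi-start search, although made
substantially more robust by screening, symmetry restarts and valley descent,
has no global-optimality guarantee on these nonconvex surfaces — pathological
seeds can still require a larger start budget; lifetime analysis is limited
to two components with no repetition-rate wraparound; and the redundancy
filter approximates isoform removal by exact-duplicate and fragment rules
only.
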