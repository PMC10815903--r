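Package: tdtkinetics
Title: Pre-Steady-State Kinetic Analysis of Terminal Deoxynucleotidyl Transferase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action modelling and global fitting of transient-kinetic data for
    template-independent DNA polymerisation by terminal deoxynucleotidyl transferase
    (TdT). Provides declarative two-step nucleotide-binding reaction schemes with an
    irreversible chemistry step, compilation to mass-action ODE systems with
    conserved-moiety accounting, forward simulation of stopped-flow fluorescence
    observables with photobleaching, variable-projection global fitting of rate
    constants across concentration series, quench-flow single-exponential and
    hyperbolic (kpol/Kd) analysis, time-correlated single-photon-counting lifetime
    fitting by instrument-response reconvolution with model selection, alignment
    column conservation profiling of the dNTP-binding pocket, and seeded synthetic
    data generators emulating the experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    Biostrings,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
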