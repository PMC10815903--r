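#!/usr/bin/env Rscript
# Stage 6: mutant relative-activity comparison. Generates wild-type and
# double-mutant-like CPy traces (the mutant accelerates the dye-binding,
# catalytic-complex and addition phases by 4-, 13- and 16-fold), fits each to
# a sum of three exponentials, and reports per-phase activity ratios.
# Writes results/mutant_activity.csv.

suppressPackageStartupMessages(library(tdtkinetics))
dir.create("results", showWarnings = FALSE)

truth <- mutant_activity_truth()
wt_tr <- gen_multiexp_trace(truth$wt_kobs, truth$amplitudes, truth$offset,
                            noise_sigma = 0.01, seed = 1, id = "WT")
mut_tr <- gen_multiexp_trace(truth$wt_kobs * truth$mutant_factors,
                             truth$amplitudes, truth$offset,
                             noise_sigma = 0.01, seed = 2, id = "D395N/E456N-like")

wt <- fit_multiexponential(wt_tr, 3, seed = 1)
mut <- fit_multiexponential(mut_tr, 3, seed = 1)
ratios <- relative_activity(mut, wt)

phases <- c("dye binding", "catalytic complex", "addition")
tab <- data.frame(phase = phases,
                  kobs_wt = wt$kobs, kobs_mutant = mut$kobs,
                  ratio = ratios, truth_factor = truth$mutant_factors)
print(tab, digits = 4)
write.csv(tab, "results/mutant_activity.csv", row.names = FALSE)
cat("wrote results/mutant_activity.csv\n")
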