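#!/usr/bin/env Rscript
# Stage 6: labelling-density calibration. Bouton maps -> labelled fraction
# -> expected labelled fibres per Purkinje cell, with a plausibility
# t-test against direct counts.

suppressPackageStartupMessages(library(pfclust))
set.seed(20260925)

params <- density_params()
fracs <- vapply(1:5, function(k) {
  m <- read_points(sprintf("scratch/data/bouton_map_%d.csv", k))
  estimate_labelled_fraction(m, params)$fraction
}, numeric(1))

frac_hat <- mean(fracs)
expected <- expected_pf_count_per_pc(frac_hat, params)

# direct counts in Purkinje-cell-tree-sized areas (simulated at the truth)
direct <- rpois(12, 0.0038 * params$pfs_per_pc)
check <- plausibility_check(direct, expected)

write_report(list(
  per_map_fraction = fracs,
  labelled_fraction = frac_hat,
  expected_pf_per_pc = expected,
  direct_counts_mean = check$mean_observed,
  plausibility_t = check$t,
  plausibility_p = check$p_value
), "results/density.json")
cat(sprintf("labelled fraction %.4f%% -> %d PFs per Purkinje cell expected\n",
            100 * frac_hat, expected))
cat(sprintf("direct counts mean %.0f; t = %.2f, p = %.2f\n",
            check$mean_observed, check$t, check$p_value))
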