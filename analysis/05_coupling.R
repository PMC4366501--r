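#!/usr/bin/env Rscript
# Stage 5: trial-to-trial coupling of co-active fibre pairs. Pearson
# correlation of binary response rasters gives each pair a "probability of
# independence"; pairs below 0.05 are classified as coupled (likely shared
# mossy-fibre drive). Also: does coupling, or clustering of the remaining
# independent pairs, depend on distance?

suppressPackageStartupMessages(library(pfclust))

truth <- jsonlite::read_json("scratch/data/ground_truth.json",
                             simplifyVector = TRUE)
fovs <- lapply(seq_len(truth$n_fov), function(i) {
  pattern <- read_points(sprintf("scratch/data/fov_%02d_points.csv", i))
  list(pattern = pattern,
       responsive = pattern$labels == "responding",
       raster = read_raster(sprintf("scratch/data/fov_%02d_raster.csv", i)),
       fov_id = i)
})

pairs <- coupling_pairs(fovs)
write.csv(pairs, "results/coupling_pairs.csv", row.names = FALSE)

cf <- coupled_fraction(pairs)
ivd <- independence_vs_distance(pairs)
ipc <- independent_pair_clustering(pairs, fovs)

write_report(list(
  n_pairs = cf$n_total, n_determinate = cf$n_determinate,
  n_coupled = cf$n_coupled, coupled_fraction = cf$fraction,
  spearman_rho = ivd$spearman_rho, spearman_p = ivd$spearman_p,
  coupled_vs_independent_distance_p = ivd$mw_p,
  independent_median_um = ipc$median_a, all_median_um = ipc$median_b,
  independent_clustering_p = ipc$p_value
), "results/coupling.json")
cat(sprintf("coupled: %d of %d determinate pairs (%.1f%%)\n",
            cf$n_coupled, cf$n_determinate, 100 * cf$fraction))
cat(sprintf("independence vs distance: Spearman rho = %.3f (p = %.2g)\n",
            ivd$spearman_rho, ivd$spearman_p))
cat(sprintf("independent pairs still clustered: median %.1f vs %.1f um (p = %.2g)\n",
            ipc$median_a, ipc$median_b, ipc$p_value))
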