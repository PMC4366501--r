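#!/usr/bin/env Rscript
# Stage 4: nearest-neighbour Monte Carlo tests of spatial randomness on
# per-FOV maps of responding fibres, and on a stitched molecular-layer
# map, including the doubled-area robustness check.

suppressPackageStartupMessages(library(pfclust))

truth <- jsonlite::read_json("scratch/data/ground_truth.json",
                             simplifyVector = TRUE)
patterns <- lapply(seq_len(truth$n_fov), function(i) {
  read_points(sprintf("scratch/data/fov_%02d_points.csv", i))
})

# per-FOV tests on maps with enough responding fibres
rows <- list()
for (i in seq_along(patterns)) {
  resp <- subset_pattern(patterns[[i]], "responding")
  if (npoints(resp) < 3L) next
  res <- csr_monte_carlo_test(resp, n_replicates = 10000, seed = 1000L + i)
  rows[[length(rows) + 1L]] <- data.frame(
    fov = i, n_responding = npoints(resp),
    observed_mean_nnd = res$observed_mean_nnd, null_mean = res$null_mean,
    direction = res$direction, p = res$p_value)
}
per_fov <- do.call(rbind, rows)
write.csv(per_fov, "results/spatial_per_fov.csv", row.names = FALSE)

# stitched map across the first six FOVs with responders, laid side by side
with_resp <- which(vapply(patterns, function(p) {
  sum(p$labels == "responding") >= 1L
}, logical(1)))[1:6]
fov_w <- patterns[[1]]$region[3]
stitched <- stitch_activity_map(
  lapply(patterns[with_resp], subset_pattern, which = "responding"),
  offsets = cbind((seq_along(with_resp) - 1L) * fov_w, 0))
res_map <- csr_monte_carlo_test(stitched, n_replicates = 10000, seed = 77)
res_map2 <- csr_monte_carlo_test(stitched, n_replicates = 10000, seed = 78,
                                 region = region_convention(
                                   stitched, "in_vivo", area_multiplier = 2))

write_report(list(
  n_maps_tested = nrow(per_fov),
  n_significant_clustered = sum(per_fov$p < 0.05 &
                                  per_fov$direction == "clustered"),
  stitched = list(n = npoints(stitched), p = res_map$p_value,
                  direction = res_map$direction),
  stitched_doubled_area = list(p = res_map2$p_value,
                               direction = res_map2$direction)
), "results/spatial_maps.json")
cat(sprintf("%d/%d per-FOV maps significantly clustered (p < 0.05)\n",
            sum(per_fov$p < 0.05 & per_fov$direction == "clustered"),
            nrow(per_fov)))
cat(sprintf("stitched map (%d fibres): %s, p = %.4g; doubled area: %s, p = %.4g\n",
            npoints(stitched), res_map$direction, res_map$p_value,
            res_map2$direction, res_map2$p_value))
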