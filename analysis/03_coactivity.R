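#!/usr/bin/env Rscript
# Stage 3: is the number and spacing of co-active fibres compatible with
# independent activation? Binomial null + chi-square on counts per field
# of view; Mann-Whitney and a 99.9% bootstrap CDF envelope on pair
# distances.

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

n_labelled <- vapply(fovs, function(f) length(f$responsive), integer(1))
observed <- vapply(fovs, function(f) sum(f$responsive), integer(1))
p_hat <- estimate_p_response(observed, n_labelled)
null <- binomial_null(n_labelled, p_hat)
chisq <- coactivity_test(observed, null)

d <- coactive_pair_distances(fovs)
mw <- compare_distance_distributions(d$active, d$all)
env <- distance_cdf_envelope(d$all, length(d$active), n_boot = 10000,
                             seed = 99,
                             grid = seq(0, max(d$all), length.out = 200))
active_cdf <- stats::ecdf(d$active)(env$grid)
exits <- sum(active_cdf > env$upper | active_cdf < env$lower)

write.csv(data.frame(grid_um = env$grid, expected = env$expected_cdf,
                     lower = env$lower, upper = env$upper,
                     active = active_cdf),
          "results/coactivity_cdf_envelope.csv", row.names = FALSE)
write_report(list(p_response_hat = p_hat,
                  chisq = chisq[c("statistic", "df", "p_value")],
                  median_active_um = mw$median_a,
                  median_all_um = mw$median_b,
                  mw_p = mw$p_value,
                  envelope_exits = exits),
             "results/coactivity.json")
cat(sprintf("p_response = %.4f; chi-square X2 = %.1f (df %d), p = %.2g\n",
            p_hat, chisq$statistic, chisq$df, chisq$p_value))
cat(sprintf("median pair distance: active %.1f um vs all %.1f um (MW p = %.2g); CDF exits envelope at %d grid points\n",
            mw$median_a, mw$median_b, mw$p_value, exits))
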