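#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Builds a ground-truthed stand-in for a sparse parallel-fibre imaging
# experiment: 85 fields of view with labelled-fibre positions and response
# rasters (with a shared-driver subpopulation), dF/F traces for a handful
# of fibres, and bouton maps for the density calibration. Everything is
# written through the package's file contracts so later stages exercise
# the same I/O path an external dataset would use.

suppressPackageStartupMessages(library(pfclust))
set.seed(20260924)
dir.create("scratch/data", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(coupling = list(group_size = 3, reliability = 0.8,
                                         trial_reliability = 0.5))
sim <- simulate_population_experiment(cfg, n_fov = 85,
                                      clustered_responders = TRUE,
                                      seed = NULL)

for (f in sim$fovs) {
  write_points(f$pattern, sprintf("scratch/data/fov_%02d_points.csv", f$fov_id))
  write_raster(f$raster, sprintf("scratch/data/fov_%02d_raster.csv", f$fov_id))
}
write_report(list(n_fov = length(sim$fovs),
                  n_fibres = sum(labelled_counts(sim)),
                  n_responsive = sum(responder_counts(sim)),
                  truth_groups = sim$truth$groups,
                  truth_responsive = sim$truth$responsive),
             "scratch/data/ground_truth.json")

# traces for ten spontaneously active, responsive fibres (120 s at 32 Hz)
cfg_tr <- simulation_config(noise_sd_dff = 0.07)
spk <- simulate_spike_trains(cfg_tr, n_fibres = 10, duration_s = 120,
                             stimulus_times = seq(2, 117, by = 5),
                             responsive = rep(TRUE, 10),
                             spontaneous = rep(TRUE, 10), seed = NULL)
traces <- simulate_traces(cfg_tr, spk, seed = NULL)
write_traces(traces, "scratch/data/traces.csv")
write_report(list(spike_times = spk$spike_times,
                  responded = apply(spk$responded, 1L, which)),
             "scratch/data/traces_truth.json")

# bouton maps at the known labelled fraction
for (k in 1:5) {
  m <- simulate_bouton_map(0.0038, density_params(), c(0, 0, 100, 100),
                           seed = NULL)
  write_points(m$pattern, sprintf("scratch/data/bouton_map_%d.csv", k))
}

cat(sprintf("simulated %d FOVs (%d fibres, %d responsive), 10 traces, 5 bouton maps\n",
            length(sim$fovs), sum(labelled_counts(sim)),
            sum(responder_counts(sim))))
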