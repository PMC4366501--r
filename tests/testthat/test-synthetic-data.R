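test_that("the generator is deterministic given a seed", {
  cfg <- simulation_config(seed = 5, pattern_kind = "thomas_cluster")
  a <- simulate_point_pattern(cfg)
  b <- simulate_point_pattern(cfg)
  expect_identical(a, b)
  sim1 <- simulate_population_experiment(simulation_config(seed = 7),
                                         n_fov = 5)
  sim2 <- simulate_population_experiment(simulation_config(seed = 7),
                                         n_fov = 5)
  expect_identical(sim1, sim2)
  tr1 <- simulate_traces(simulation_config(seed = 9), list(c(1, 2.5)),
                         duration_s = 5)
  tr2 <- simulate_traces(simulation_config(seed = 9), list(c(1, 2.5)),
                         duration_s = 5)
  expect_identical(tr1[[1]]$samples, tr2[[1]]$samples)
})

test_that("point-pattern generators have the advertised geometry", {
  cfg <- simulation_config(seed = 1)
  # empty CSR pattern
  empty <- simulate_point_pattern(cfg, n = 0)
  expect_equal(npoints(empty$pattern), 0L)
  # regular lattice with zero jitter: 25 points in 50x50 um -> spacing 10
  cfg_reg <- simulation_config(seed = 2, pattern_kind = "regular",
                               regular_jitter_frac = 0,
                               region_width_um = 50, region_height_um = 50)
  lat <- simulate_point_pattern(cfg_reg, n = 25)
  expect_equal(mean_nn_distance(lat$pattern), 10)
  # Thomas process: exact count, all offspring inside, truth recorded
  cfg_th <- simulation_config(seed = 3, pattern_kind = "thomas_cluster",
                              cluster_params = list(n_parents = 5,
                                                    offspring_per_parent = 4,
                                                    sigma_um = 3),
                              region_width_um = 100, region_height_um = 100)
  th <- simulate_point_pattern(cfg_th)
  expect_equal(npoints(th$pattern), 20L)
  expect_length(th$truth$parent_id, 20L)
  expect_identical(th$truth$pattern_kind, "thomas_cluster")
})

test_that("Thomas patterns sit below the matched-n CSR mean NND", {
  cfg_th <- simulation_config(pattern_kind = "thomas_cluster",
                              cluster_params = list(n_parents = 5,
                                                    offspring_per_parent = 4,
                                                    sigma_um = 3),
                              region_width_um = 100, region_height_um = 100)
  set.seed(41)
  th_mean <- mean(replicate(200, {
    mean_nn_distance(simulate_point_pattern(cfg_th, seed = NULL)$pattern)
  }))
  # CSR expectation for n = 20 in the same region, by Monte Carlo
  cfg_csr <- simulation_config(region_width_um = 100, region_height_um = 100)
  csr_mean <- mean(replicate(500, {
    mean_nn_distance(simulate_point_pattern(cfg_csr, n = 20,
                                            seed = NULL)$pattern)
  }))
  expect_lt(th_mean, csr_mean)
})

test_that("CSR intensity matches nominal over many replicates", {
  cfg <- simulation_config(n_fibres_per_fov = 4:21)
  set.seed(51)
  counts <- replicate(1000, npoints(simulate_point_pattern(cfg,
                                                           seed = NULL)$pattern))
  expect_lt(abs(mean(counts) - mean(4:21)), 3 * sd(counts) / sqrt(1000))
})

test_that("shared-driver algebra keeps the marginal response probability", {
  # singleton groups: independent Bernoulli at the marginal
  m1 <- simulate_correlated_binary(1:50, 400, p_drive = 0.3, reliability = 1,
                                   p_marginal = 0.3, seed = 1)
  expect_lt(abs(mean(m1) - 0.3), 3 * sqrt(0.3 * 0.7 / length(m1)))
  # grouped fibres keep the marginal despite shared drive
  m2 <- simulate_correlated_binary(rep(1:10, each = 3), 4000, p_drive = 0.25,
                                   reliability = 0.8, p_marginal = 0.3,
                                   seed = 2)
  expect_lt(abs(mean(m2) - 0.3), 3 * sqrt(0.3 * 0.7 / length(m2)))
  # full coupling: identical columns, r = 1
  m3 <- simulate_correlated_binary(c(1, 1), 200, p_drive = 0.028,
                                   reliability = 1, p_marginal = 0.028,
                                   seed = 3)
  expect_identical(m3[1, ], m3[2, ])
  # unreachable marginal is an error
  expect_error(simulate_correlated_binary(c(1, 1), 10, p_drive = 0.5,
                                          reliability = 1, p_marginal = 0.1),
               "not achievable")
})

test_that("independent fibres have null pairwise correlations", {
  set.seed(61)
  cfg <- simulation_config(coupling = list(group_size = 1, reliability = 0.8,
                                           trial_reliability = 0.5))
  sim <- simulate_population_experiment(cfg, n_fov = 20, seed = 71)
  rs <- c()
  for (f in sim$fovs) {
    n <- nrow(f$raster$responses)
    resp <- which(f$responsive)
    if (length(resp) >= 2L) {
      rs <- c(rs, cor(f$raster$responses[resp[1], ],
                      f$raster$responses[resp[2], ]))
    }
  }
  # few FOVs have 2+ responders at p = 0.028; top up with direct rasters
  m <- simulate_correlated_binary(1:2, 200, 0.5, 1, 0.5, seed = 81)
  rs <- c(rs, replicate(200, {
    m <- matrix(runif(400) < 0.5, 2)
    cor(m[1, ], m[2, ])
  }))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("trace forward model produces the advertised transients", {
  cfg <- simulation_config(noise_sd_dff = 0)
  # zero spikes, zero noise: identically zero
  tr0 <- simulate_traces(cfg, list(numeric(0)), duration_s = 2, seed = 1)
  expect_identical(tr0[[1]]$samples, numeric(64))
  # single spike: instantaneous rise to ~amplitude, exponential decay
  cfg1 <- simulation_config(noise_sd_dff = 0,
                            event_amplitude_dff = c(0.5, 0))
  tr1 <- simulate_traces(cfg1, list(1), duration_s = 3, seed = 2)[[1]]
  peak_idx <- which.max(tr1$samples)
  expect_equal((peak_idx - 1) / 32, 1, tolerance = 1 / 32)
  expect_equal(max(tr1$samples), 0.5, tolerance = 0.02)
  # decay by tau: value one tau after the peak is ~ amp / e
  tau_frames <- round(0.3 * 32)
  expect_equal(tr1$samples[peak_idx + tau_frames] / max(tr1$samples),
               exp(-tau_frames / (0.3 * 32)), tolerance = 0.02)
  # amplitude floor: no event below 0.05 dF/F
  cfg2 <- simulation_config(noise_sd_dff = 0,
                            event_amplitude_dff = c(0.05, 0.3))
  tr2 <- simulate_traces(cfg2, list(seq(0.5, 19.5, 1)), duration_s = 20,
                         seed = 3)[[1]]
  expect_true(all(attr(tr2, "amplitudes") >= 0.05))
})

test_that("evoked bursts respect the intra-burst frequency cap", {
  cfg <- simulation_config(seed = 91)
  tr <- simulate_spike_trains(cfg, n_fibres = 40, duration_s = 30,
                              stimulus_times = seq(1, 29, 5),
                              responsive = rep(TRUE, 40),
                              spontaneous = rep(FALSE, 40))
  for (i in seq_len(40)) {
    st <- tr$spike_times[[i]]
    if (length(st) >= 2L) {
      isi <- diff(st)
      intra <- isi[isi < 0.5] # within-burst intervals
      if (length(intra)) {
        expect_gte(min(intra), 1 / cfg$max_intraburst_freq_hz - 1e-9)
        expect_lte(max(intra), 3 / cfg$max_intraburst_freq_hz + 1e-9)
      }
    }
  }
  # burst sizes come from the configured distribution support
  expect_true(all(unlist(tr$burst_sizes) %in% 1:4))
  # latencies are non-negative and in the tens of milliseconds
  lats <- unlist(tr$latencies_ms)
  expect_true(all(lats >= 0 & lats < 50))
})

test_that("bouton maps have the closed-form expected count", {
  # fraction 0 -> empty
  m0 <- simulate_bouton_map(0, density_params(), c(0, 0, 100, 100), seed = 1)
  expect_equal(npoints(m0$pattern), 0L)
  # closed form: 0.0038 * 5.5 * 10000 / 3.7 ~ 56.5
  m <- simulate_bouton_map(0.0038, density_params(), c(0, 0, 100, 100),
                           seed = 2)
  expect_equal(m$truth$expected_count, 0.0038 * 5.5 * 1e4 / 3.7,
               tolerance = 1e-12)
  set.seed(3)
  counts <- replicate(300, npoints(simulate_bouton_map(
    0.0038, density_params(), c(0, 0, 100, 100))$pattern))
  expect_lt(abs(mean(counts) - m$truth$expected_count),
            3 * sd(counts) / sqrt(300))
  # thick sections are rejected
  expect_error(simulate_bouton_map(0.01, density_params(section_thickness_um = 5),
                                   c(0, 0, 100, 100)),
               "not supported")
})
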