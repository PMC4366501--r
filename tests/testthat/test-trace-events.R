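test_that("dF/F conversion is exact for known baselines", {
  # constant trace at F0: all-zero dF/F
  tr <- pf_trace(rep(80, 128), 32, units = "raw")
  expect_equal(compute_dff(tr, function(x) 80)$samples, rep(0, 128))
  # doubling F0 at one sample gives dF/F = 1 there
  x <- rep(80, 128)
  x[60] <- 160
  d <- compute_dff(pf_trace(x, 32, units = "raw"), function(x) 80)
  expect_equal(d$samples[60], 1)
  expect_equal(d$samples[-60], rep(0, 127))
  # non-positive baseline is rejected with the offending window named
  expect_error(compute_dff(pf_trace(c(rep(5, 64), rep(-1, 64)), 32,
                                    units = "raw"),
                           baseline_window_s = 1),
               "F0 <= 0")
  expect_error(compute_dff(pf_trace(rep(0.1, 64), 32, units = "dff")),
               "raw trace")
})

test_that("dF/F round trip recovers the generator output", {
  cfg <- simulation_config(seed = 8)
  spk <- simulate_spike_trains(cfg, 1, 30, stimulus_times = numeric(0),
                               responsive = FALSE, spontaneous = TRUE)
  dff <- simulate_traces(cfg, spk)[[1]]
  f0 <- 120
  raw <- pf_trace((1 + dff$samples) * f0, 32, units = "raw")
  rec <- compute_dff(raw, function(x) f0)
  expect_equal(rec$samples, dff$samples, tolerance = 1e-10)
})

test_that("Fourier high-pass removes slow components, keeps transients", {
  fs <- 32
  # pure DC offset vanishes
  hp <- highpass_detrend(pf_trace(rep(0.5, fs * 20), fs, units = "dff"), 0.5)
  expect_lt(max(abs(hp$samples)), 1e-12)
  # slow sine (integer periods, below cutoff) + fast transient
  t <- (0:(fs * 120 - 1)) / fs
  sine <- 0.3 * sin(2 * pi * t / 60) # 1/60 Hz, 2 full periods
  trans <- 0.5 * exp(-pmax(t - 60, 0) / 0.3) * (t >= 60)
  hp2 <- highpass_detrend(pf_trace(sine + trans, fs, units = "dff"), 0.05)
  expect_lt(max(abs(hp2$samples[t < 50])), 0.02) # sine gone
  # transient preserved within 5% of its amplitude
  expect_equal(max(hp2$samples[t >= 60 & t < 61]), 0.5, tolerance = 0.05)
  expect_lt(abs(mean(hp2$samples)), 1e-12)
  # Parseval: white-noise variance drops by the removed band's share
  set.seed(12)
  x <- rnorm(fs * 60)
  hp3 <- highpass_detrend(pf_trace(x, fs, units = "dff"), 4)
  expect_equal(var(hp3$samples) / var(x), 1 - 2 * 4 / fs, tolerance = 0.05)
  expect_error(highpass_detrend(pf_trace(x, fs, units = "dff"), 16),
               "Nyquist")
})

test_that("event detection respects the two-s.d. criterion", {
  # flat zero trace: nothing to detect
  ev0 <- detect_events(pf_trace(numeric(256), 32, units = "dff"))
  expect_length(ev0$onset_times, 0L)
  # a single excursion at 1.9 noise s.d. stays below threshold
  set.seed(21)
  x <- rnorm(64 * 32, 0, 0.07)
  x[1000] <- 1.9 * 0.07
  ev <- detect_events(pf_trace(x, 32, units = "dff"))
  expect_false(any(abs(ev$onset_times - 999 / 32) < 3 / 32))
  # five well-separated transients at SNR ~ 7 are all found within 1 frame
  cfg <- simulation_config(noise_sd_dff = 0.07,
                           event_amplitude_dff = c(0.5, 0))
  true_t <- c(2, 6, 10, 14, 18)
  tr <- simulate_traces(cfg, list(true_t), duration_s = 22, seed = 23)[[1]]
  ev5 <- detect_events(tr)
  m <- match_events(ev5$onset_times, true_t, tol_s = 1.001 / 32)
  expect_equal(m$tp, 5L)
  expect_equal(m$fp + m$fn, 0L)
})

test_that("detection is translation equivariant and scale invariant", {
  cfg <- simulation_config(noise_sd_dff = 0.07,
                           event_amplitude_dff = c(0.5, 0))
  tr <- simulate_traces(cfg, list(c(3, 8, 13)), duration_s = 20,
                        seed = 31)[[1]]
  ev <- detect_events(tr)
  # shift by an integer number of frames (rotate the sample vector)
  k <- 64L
  shifted <- pf_trace(c(tr$samples[(length(tr$samples) - k + 1):
                                     length(tr$samples)],
                        tr$samples[1:(length(tr$samples) - k)]),
                      32, units = "dff")
  ev_s <- detect_events(shifted)
  expect_equal(sort(ev_s$onset_times), sort(ev$onset_times + k / 32),
               tolerance = 1e-9)
  # common scaling of signal and noise changes nothing
  scaled <- pf_trace(tr$samples * 3.7, 32, units = "dff")
  ev_sc <- detect_events(scaled)
  expect_equal(ev_sc$onset_times, ev$onset_times)
  expect_equal(ev_sc$snr, ev$snr, tolerance = 1e-9)
})

test_that("false-positive rate on pure noise stays under the union bound", {
  set.seed(41)
  p <- detection_params()
  n_frames <- 3840L
  bound_per_trace <- n_frames *
    (p$evidence_max_frames - p$min_event_duration_frames + 1) *
    pnorm(-p$evidence_z)
  fps <- replicate(15, {
    length(detect_events(pf_trace(rnorm(n_frames, 0, 0.07), 32,
                                  units = "dff"))$onset_times)
  })
  expect_lt(mean(fps), bound_per_trace)
})

test_that("detection recovers ground truth in the SNR~7 regime", {
  cfg <- simulation_config(noise_sd_dff = 0.07,
                           event_amplitude_dff = c(0.5, 0))
  set.seed(51)
  tp <- fp <- fn <- 0
  errors <- c()
  for (i in 1:8) {
    true_t <- seq(1, 118, by = 2) + runif(59, 0, 0.5)
    tr <- simulate_traces(cfg, list(true_t), duration_s = 120,
                          seed = NULL)[[1]]
    m <- match_events(detect_events(tr)$onset_times, true_t,
                      tol_s = 1.001 / 32)
    tp <- tp + m$tp
    fp <- fp + m$fp
    fn <- fn + m$fn
    errors <- c(errors, m$errors)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
})

test_that("detection degrades gracefully under amplitude dispersion", {
  # with the full amplitude distribution (0.50 +/- 0.25, floored), part of
  # the events fall below the 2-s.d. criterion itself; recovery of the
  # detectable events stays high
  cfg <- simulation_config(noise_sd_dff = 0.07)
  set.seed(61)
  det <- miss <- 0
  for (i in 1:6) {
    true_t <- seq(1, 118, by = 2) + runif(59, 0, 0.5)
    tr <- simulate_traces(cfg, list(true_t), duration_s = 120,
                          seed = NULL)[[1]]
    amps <- attr(tr, "amplitudes")
    ev <- detect_events(tr)
    used <- rep(FALSE, length(ev$onset_times))
    for (k in seq_along(true_t)) {
      d <- abs(ev$onset_times - true_t[k])
      d[used] <- Inf
      j <- which.min(d)
      hit <- length(d) && is.finite(d[j]) && d[j] <= 1.5 / 32
      if (hit) used[j] <- TRUE
      if (amps[k] >= 2 * 0.07) {
        if (hit) det <- det + 1 else miss <- miss + 1
      }
    }
  }
  expect_gte(det / (det + miss), 0.9)
})

test_that("response classification applies the window and the 2-s.d. STA rule", {
  cfg <- simulation_config(noise_sd_dff = 0.07,
                           event_amplitude_dff = c(0.56, 0))
  # no events at all: all trials false, fibre is a non-responder
  set.seed(71)
  quiet <- pf_trace(rnorm(32 * 60, 0, 0.07), 32,
                    stimulus_times = seq(2, 52, 5), units = "dff")
  no_events <- detect_events(pf_trace(numeric(32 * 60), 32, units = "dff"))
  r0 <- classify_responses(quiet, events = no_events)
  expect_false(any(r0$per_trial))
  expect_false(r0$responder)
  # an event 400 ms after the stimulus is outside a 200 ms window
  tr <- simulate_traces(cfg, list(10.4), duration_s = 20, seed = 72)[[1]]
  tr$stimulus_times <- 10
  r1 <- classify_responses(tr)
  expect_false(r1$per_trial[1])
  # overlapping response windows are rejected
  tr$stimulus_times <- c(10, 10.1)
  expect_error(classify_responses(tr), "smaller")
})

test_that("per-trial response classification is accurate at SNR ~ 8", {
  cfg <- simulation_config(noise_sd_dff = 0.07,
                           event_amplitude_dff = c(0.56, 0),
                           coupling = list(group_size = 1, reliability = 0.8,
                                           trial_reliability = 0.5))
  set.seed(81)
  correct <- total <- 0
  responders <- 0
  for (i in 1:10) {
    spk <- simulate_spike_trains(cfg, 1, 210, stimulus_times = seq(2, 202, 5),
                                 responsive = TRUE, spontaneous = FALSE,
                                 seed = NULL)
    tr <- simulate_traces(cfg, spk, seed = NULL)[[1]]
    r <- classify_responses(tr)
    correct <- correct + sum(r$per_trial == spk$responded[1, ])
    total <- total + length(r$per_trial)
    responders <- responders + r$responder
  }
  expect_gte(correct / total, 0.95)
  expect_equal(responders, 10) # every simulated fibre is a true responder
})

test_that("SNR summaries follow their definition and pool correctly", {
  ev <- structure(list(onset_times = c(1, 2), peak_amplitudes = c(0.5, 0.5),
                       snr = c(5, 5), noise_sd = 0.1, sampling_rate = 32,
                       roi_id = 1), class = "pf_events")
  s <- compute_snr(ev)
  expect_equal(s$mean_snr, 5)
  expect_equal(s$per_event$normalized_amplitude, c(1, 1))
  # pooled SNR from the generator regime lands in the observed-in-vivo range
  cfg <- simulation_config(noise_sd_dff = 0.07)
  set.seed(91)
  evs <- lapply(1:6, function(i) {
    true_t <- seq(1, 118, by = 2) + runif(59, 0, 0.5)
    detect_events(simulate_traces(cfg, list(true_t), duration_s = 120,
                                  seed = NULL)[[1]])
  })
  pooled <- compute_snr(evs)
  expect_gte(pooled$mean_snr, 6)
  expect_lte(pooled$mean_snr, 9)
})

test_that("burst decomposition counts steps and calibrates frequency", {
  cfg <- simulation_config(noise_sd_dff = 0.02,
                           event_amplitude_dff = c(0.5, 0))
  # a single clean step: one event, frequency undefined
  tr1 <- simulate_traces(cfg, list(0.5), duration_s = 1,
                         sampling_rate = 1000, seed = 11)[[1]]
  b1 <- decompose_burst(tr1, stimulus_time = 0.49)
  expect_equal(b1$n_events, 1L)
  expect_true(is.na(b1$max_freq_hz))
  # three steps 6 ms apart: ~167 Hz (no smoothing needed at this noise)
  tr3 <- simulate_traces(cfg, list(c(0.5, 0.506, 0.512)), duration_s = 1,
                         sampling_rate = 1000, seed = 12)[[1]]
  b3 <- decompose_burst(tr3, stimulus_time = 0.49, smooth_frames = 1)
  expect_equal(b3$n_events, 3L)
  expect_equal(b3$max_freq_hz, 1000 / 6, tolerance = 1e-9)
  # population-rate data are rejected
  slow <- pf_trace(rnorm(320, 0, 0.07), 32, units = "dff")
  expect_error(decompose_burst(slow, stimulus_time = 1), "500")
})

test_that("burst size recovery is exact in most trials at SNR ~ 8", {
  cfg <- simulation_config(noise_sd_dff = 0.07,
                           event_amplitude_dff = c(0.56, 0))
  set.seed(13)
  exact <- 0
  n <- 100
  for (i in 1:n) {
    k <- sample(2:3, 1)
    spk <- 0.3 + runif(1, 0, 0.01) +
      c(0, cumsum(runif(k - 1, 1 / 172, 3 / 172)))
    tr <- simulate_traces(cfg, list(spk), duration_s = 1,
                          sampling_rate = 1000, seed = NULL)[[1]]
    b <- decompose_burst(tr, stimulus_time = 0.29)
    exact <- exact + (b$n_events == k)
  }
  expect_gte(exact / n, 0.9)
})

test_that("latency distributions expose bimodality when present", {
  # identical latencies: a single occupied bin
  ld0 <- latency_distribution(rep(10, 20), fit = FALSE)
  expect_equal(sum(ld0$counts > 0), 1L)
  # generator mixture: component means recovered within 2 ms
  set.seed(14)
  comp <- sample(1:2, 200, replace = TRUE)
  lat <- ifelse(comp == 1, rnorm(200, 10, 2), rnorm(200, 22, 3))
  ld <- latency_distribution(lat)
  expect_equal(ld$component_means[1], 10, tolerance = 2)
  expect_equal(ld$component_means[2], 22, tolerance = 2)
  expect_true(ld$bimodal)
  # unimodal input is flagged as not bimodal
  ld1 <- latency_distribution(rnorm(200, 15, 3))
  expect_false(ld1$bimodal)
})
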