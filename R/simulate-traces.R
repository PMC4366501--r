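#' Simulate ground-truth spike (event) times for a set of fibres
#'
#' Spontaneous events follow a homogeneous Poisson process at
#' `spontaneous_rate_hz` in the spontaneously active subset of fibres.
#' Responsive fibres additionally emit an evoked burst after each effective
#' stimulus (per-trial probability `coupling$trial_reliability`): the burst
#' latency is drawn from the two-component Gaussian latency mixture, the
#' number of events in the burst from `burst_size_dist`, and intra-burst
#' intervals uniformly from `[1/f_max, 3/f_max]` — consistent with bursts
#' of two or three events without committing to a specific ISI distribution.
#'
#' @param config a [simulation_config()].
#' @param n_fibres number of fibres.
#' @param duration_s trace duration (s).
#' @param stimulus_times stimulus onsets (s); default from the config's
#'   trial layout truncated to the duration.
#' @param responsive logical per fibre; default: drawn with probability
#'   `p_response`.
#' @param spontaneous logical per fibre; default: drawn with probability
#'   `frac_spontaneously_active`.
#' @param seed optional seed overriding `config$seed`.
#' @return list of class `pf_spike_truth`: per-fibre `spike_times` (sorted),
#'   per-fibre x trial `responded` matrix, `burst_sizes` and `latencies_ms`
#'   (per responded trial), plus the flags and stimulus times.
#' @export
simulate_spike_trains <- function(config, n_fibres, duration_s,
                                  stimulus_times = NULL, responsive = NULL,
                                  spontaneous = NULL, seed = config$seed) {
  stopifnot(inherits(config, "pf_sim_config"))
  check_number(duration_s, "duration_s", positive = TRUE)
  if (is.null(stimulus_times)) {
    stimulus_times <- seq(1, duration_s - 1, by = config$stimulus_interval_s)
  }
  with_seed(seed, {
    if (is.null(responsive)) {
      responsive <- runif(n_fibres) < config$p_response
    }
    if (is.null(spontaneous)) {
      spontaneous <- runif(n_fibres) < config$frac_spontaneously_active
    }
    n_trials <- length(stimulus_times)
    spikes <- vector("list", n_fibres)
    responded <- matrix(FALSE, n_fibres, max(1L, n_trials))[, seq_len(n_trials),
                                                            drop = FALSE]
    burst_sizes <- latencies <- vector("list", n_fibres)
    sizes <- as.integer(names(config$burst_size_dist))
    for (i in seq_len(n_fibres)) {
      st <- numeric(0)
      if (spontaneous[i]) {
        n_sp <- rpois(1L, config$spontaneous_rate_hz * duration_s)
        st <- runif(n_sp, 0, duration_s)
      }
      bs <- integer(0)
      lat <- numeric(0)
      if (responsive[i] && n_trials > 0L) {
        for (t in seq_len(n_trials)) {
          if (runif(1L) >= config$coupling$trial_reliability) next
          responded[i, t] <- TRUE
          comp <- sample(nrow(config$latency_mixture), 1L,
                         prob = config$latency_mixture$weight)
          l_ms <- rnorm(1L, config$latency_mixture$mean_ms[comp],
                        config$latency_mixture$sd_ms[comp])
          l_ms <- max(l_ms, 0)
          k <- sample(sizes, 1L, prob = config$burst_size_dist)
          isi <- runif(max(k - 1L, 0L), 1 / config$max_intraburst_freq_hz,
                       3 / config$max_intraburst_freq_hz)
          burst <- stimulus_times[t] + l_ms / 1000 + c(0, cumsum(isi))
          st <- c(st, burst[burst < duration_s])
          bs <- c(bs, k)
          lat <- c(lat, l_ms)
        }
      }
      spikes[[i]] <- sort(st)
      burst_sizes[[i]] <- bs
      latencies[[i]] <- lat
    }
    structure(list(spike_times = spikes, responded = responded,
                   burst_sizes = burst_sizes, latencies_ms = latencies,
                   responsive = responsive, spontaneous = spontaneous,
                   stimulus_times = stimulus_times,
                   duration_s = duration_s),
              class = "pf_spike_truth")
  })
}

#' Forward model: spikes to dF/F fluorescence traces
#'
#' Each ground-truth event adds a calcium transient with an instantaneous
#' rise and a single-exponential decay (`decay_tau_s`) to a baseline of
#' i.i.d. Gaussian noise (`noise_sd_dff`). Event amplitudes are drawn from
#' `N(mean, sd)` (per event) and truncated below at `amplitude_floor_dff`
#' so no event has non-positive amplitude. Within a burst, transients sum.
#' Output is in dF/F units.
#'
#' @param config a [simulation_config()].
#' @param truth a `pf_spike_truth` from [simulate_spike_trains()], or a list
#'   of numeric spike-time vectors.
#' @param duration_s trace duration; default from `truth`.
#' @param sampling_rate sampling rate; default `config$frame_rate_hz` (use
#'   1000 for linescans).
#' @param seed optional seed overriding `config$seed`.
#' @return list of [pf_trace()] objects (units `"dff"`), with the drawn
#'   per-event amplitudes attached as attribute `"amplitudes"`.
#' @export
simulate_traces <- function(config, truth, duration_s = NULL,
                            sampling_rate = config$frame_rate_hz,
                            seed = config$seed) {
  stopifnot(inherits(config, "pf_sim_config"))
  if (inherits(truth, "pf_spike_truth")) {
    spikes <- truth$spike_times
    if (is.null(duration_s)) duration_s <- truth$duration_s
    stim <- truth$stimulus_times
  } else {
    spikes <- truth
    if (is.null(duration_s)) {
      stop_pf("`duration_s` required when `truth` is a bare spike list")
    }
    stim <- numeric(0)
  }
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  n_samp <- round(duration_s * sampling_rate)
  tgrid <- (seq_len(n_samp) - 1L) / sampling_rate
  amp_mean <- config$event_amplitude_dff[[1]]
  amp_sd <- config$event_amplitude_dff[[2]]
  with_seed(seed, {
    lapply(seq_along(spikes), function(i) {
      x <- if (config$noise_sd_dff > 0) {
        rnorm(n_samp, 0, config$noise_sd_dff)
      } else {
        numeric(n_samp)
      }
      st <- spikes[[i]]
      amps <- pmax(rnorm(length(st), amp_mean, amp_sd),
                   config$amplitude_floor_dff)
      for (k in seq_along(st)) {
        idx <- which(tgrid >= st[k])
        if (length(idx)) {
          x[idx] <- x[idx] + amps[k] *
            exp(-(tgrid[idx] - st[k]) / config$decay_tau_s)
        }
      }
      tr <- pf_trace(x, sampling_rate, stimulus_times = stim, units = "dff",
                     roi_id = i)
      attr(tr, "amplitudes") <- amps
      tr
    })
  })
}
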