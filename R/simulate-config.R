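#' Configuration for the synthetic parallel-fibre experiment generator
#'
#' Bundles every parameter of the forward model. Defaults emulate the
#' statistical structure of sparse in vivo parallel-fibre recordings:
#' spontaneous firing at 0.4 Hz in ~19% of fibres, evoked response
#' probability 0.028 per fibre, evoked bursts of 1-4 events (mean 2.6) at up
#' to 172 Hz within the burst, bimodal response latency with components near
#' 10 and 22 ms, event amplitudes 0.50 +/- 0.25 dF/F over noise of
#' s.d. 0.07 dF/F (event SNR ~7), population imaging at 32 Hz, and 4-21
#' labelled fibres per 56-um field of view.
#'
#' @param seed integer seed; fully determines all generator outputs.
#' @param region_width_um,region_height_um observation region (um). The
#'   default 56 x 150 um is a sagittal molecular-layer strip the width of an
#'   imaging window.
#' @param n_fibres_per_fov single count or an integer range to sample
#'   uniformly (default `4:21`, median ~13).
#' @param p_response probability that a fibre responds to the sensory
#'   stimulus at all (fibre-level responsiveness; default 0.028).
#' @param spontaneous_rate_hz Poisson rate of spontaneous events in
#'   spontaneously active fibres (default 0.4).
#' @param frac_spontaneously_active fraction of fibres with spontaneous
#'   activity (default 0.19).
#' @param burst_size_dist named probability vector over burst sizes 1-4
#'   (default mean 2.6 events per evoked burst).
#' @param max_intraburst_freq_hz upper bound on instantaneous within-burst
#'   frequency; intra-burst intervals are drawn uniformly in
#'   `[1/f, 3/f]` (default f = 172).
#' @param latency_mixture data.frame with columns `mean_ms`, `sd_ms`,
#'   `weight` (rows = mixture components; weights must sum to 1).
#' @param event_amplitude_dff `c(mean, sd)` of event amplitudes in dF/F.
#' @param amplitude_floor_dff lower truncation of drawn amplitudes
#'   (default 0.05 dF/F, keeps events non-negative and nominally detectable).
#' @param noise_sd_dff Gaussian baseline noise s.d. in dF/F.
#' @param frame_rate_hz population imaging frame rate (default 32).
#' @param decay_tau_s calcium transient decay time constant (default 0.3 s,
#'   typical of OGB-1 in small axonal boutons).
#' @param pattern_kind `"csr"`, `"regular"` or `"thomas_cluster"`.
#' @param cluster_params list `n_parents`, `offspring_per_parent`,
#'   `sigma_um` for the Thomas cluster process.
#' @param regular_jitter_frac jitter of the regular lattice as a fraction of
#'   its spacing (default 0.1).
#' @param coupling list describing shared-driver structure:
#'   `group_size` (fibres per shared-driver group; 1 = independent),
#'   `reliability` (per-fibre response probability given group drive) and
#'   `trial_reliability` (per-trial response probability of a responsive
#'   fibre; the within-burst failure rate seen across repeated stimuli).
#' @param n_trials stimuli per experiment (default 40, i.e. 40 airpuffs).
#' @param stimulus_interval_s inter-stimulus interval (default 5 s).
#'
#' @return A list of class `pf_sim_config`.
#' @export
simulation_config <- function(seed = NULL,
                              region_width_um = 56,
                              region_height_um = 150,
                              n_fibres_per_fov = 4:21,
                              p_response = 0.028,
                              spontaneous_rate_hz = 0.4,
                              frac_spontaneously_active = 0.19,
                              burst_size_dist = c(`1` = 0.10, `2` = 0.35,
                                                  `3` = 0.40, `4` = 0.15),
                              max_intraburst_freq_hz = 172,
                              latency_mixture = data.frame(
                                mean_ms = c(10, 22),
                                sd_ms = c(2, 3),
                                weight = c(0.5, 0.5)),
                              event_amplitude_dff = c(mean = 0.50, sd = 0.25),
                              amplitude_floor_dff = 0.05,
                              noise_sd_dff = 0.07,
                              frame_rate_hz = 32,
                              decay_tau_s = 0.3,
                              pattern_kind = c("csr", "regular",
                                               "thomas_cluster"),
                              cluster_params = list(n_parents = 5,
                                                    offspring_per_parent = 3,
                                                    sigma_um = 3),
                              regular_jitter_frac = 0.1,
                              coupling = list(group_size = 1,
                                              reliability = 0.8,
                                              trial_reliability = 0.5),
                              n_trials = 40,
                              stimulus_interval_s = 5) {
  pattern_kind <- match.arg(pattern_kind)
  check_number(region_width_um, "region_width_um", positive = TRUE)
  check_number(region_height_um, "region_height_um", positive = TRUE)
  check_probability(p_response, "p_response")
  check_number(spontaneous_rate_hz, "spontaneous_rate_hz", positive = TRUE)
  check_probability(frac_spontaneously_active, "frac_spontaneously_active")
  check_number(max_intraburst_freq_hz, "max_intraburst_freq_hz",
               positive = TRUE)
  check_number(noise_sd_dff, "noise_sd_dff", min = 0)
  check_number(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  check_number(decay_tau_s, "decay_tau_s", positive = TRUE)
  stopifnot(is.numeric(n_fibres_per_fov), all(n_fibres_per_fov >= 0))
  if (abs(sum(burst_size_dist) - 1) > 1e-8) {
    stop_pf("`burst_size_dist` probabilities must sum to 1")
  }
  if (abs(sum(latency_mixture$weight) - 1) > 1e-8) {
    stop_pf("latency mixture weights must sum to 1")
  }
  if (any(latency_mixture$sd_ms <= 0)) stop_pf("latency s.d.s must be > 0")
  if (length(event_amplitude_dff) != 2L || event_amplitude_dff[2] < 0) {
    stop_pf("`event_amplitude_dff` must be c(mean, sd) with sd >= 0")
  }
  check_probability(coupling$reliability, "coupling$reliability")
  check_probability(coupling$trial_reliability, "coupling$trial_reliability")
  check_number(coupling$group_size, "coupling$group_size", positive = TRUE)
  if (pattern_kind == "thomas_cluster" && cluster_params$sigma_um <= 0) {
    stop_pf("Thomas cluster dispersion `sigma_um` must be > 0")
  }
  structure(list(
    seed = seed,
    region_width_um = region_width_um,
    region_height_um = region_height_um,
    n_fibres_per_fov = as.integer(n_fibres_per_fov),
    p_response = p_response,
    spontaneous_rate_hz = spontaneous_rate_hz,
    frac_spontaneously_active = frac_spontaneously_active,
    burst_size_dist = burst_size_dist,
    max_intraburst_freq_hz = max_intraburst_freq_hz,
    latency_mixture = latency_mixture,
    event_amplitude_dff = event_amplitude_dff,
    amplitude_floor_dff = amplitude_floor_dff,
    noise_sd_dff = noise_sd_dff,
    frame_rate_hz = frame_rate_hz,
    decay_tau_s = decay_tau_s,
    pattern_kind = pattern_kind,
    cluster_params = cluster_params,
    regular_jitter_frac = regular_jitter_frac,
    coupling = coupling,
    n_trials = as.integer(n_trials),
    stimulus_interval_s = stimulus_interval_s
  ), class = "pf_sim_config")
}

config_region <- function(config) {
  c(0, 0, config$region_width_um, config$region_height_um)
}
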