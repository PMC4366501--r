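#' Correlated Bernoulli responses through shared drivers
#'
#' Generates a units x draws boolean matrix in which units belonging to the
#' same group share a common Bernoulli driver. On each draw, group `g` is
#' driven with probability `p_drive`; a driven unit fires with probability
#' `reliability`; every unit additionally fires through an independent
#' background channel with probability `b`. The background rate is solved
#' so that the marginal per-unit probability equals `p_marginal`:
#'
#' with `q = p_drive * reliability`, the marginal is
#' `q + (1 - q) * b = p_marginal`, hence `b = (p_marginal - q) / (1 - q)`,
#' which requires `q <= p_marginal`. Singleton groups therefore give exactly
#' independent Bernoulli(`p_marginal`) units, and a group with
#' `reliability = 1` and `p_drive = p_marginal` gives identical columns.
#'
#' @param groups integer vector, group id per unit (a partition of the
#'   units; any integer labels).
#' @param n_draws number of draws (trials, or 1 for fibre-level flags).
#' @param p_drive probability a group driver is active per draw.
#' @param reliability per-unit response probability given group drive.
#' @param p_marginal target marginal per-unit response probability.
#' @param seed optional seed.
#' @return logical matrix, units x draws.
#' @export
simulate_correlated_binary <- function(groups, n_draws, p_drive, reliability,
                                       p_marginal, seed = NULL) {
  groups <- as.integer(groups)
  if (anyNA(groups)) stop_pf("`groups` must be a complete partition (no NA)")
  check_probability(p_drive, "p_drive")
  check_probability(reliability, "reliability")
  check_probability(p_marginal, "p_marginal")
  q <- p_drive * reliability
  if (q > p_marginal + 1e-12) {
    stop_pf(sprintf(
      "marginal probability %.4g not achievable: shared channel alone gives %.4g",
      p_marginal, q))
  }
  b <- if (q >= 1) 0 else (p_marginal - q) / (1 - q)
  n_units <- length(groups)
  gid <- match(groups, unique(groups))
  n_groups <- max(gid)
  with_seed(seed, {
    drive <- matrix(runif(n_groups * n_draws) < p_drive,
                    nrow = n_groups)
    via_group <- drive[gid, , drop = FALSE] &
      matrix(runif(n_units * n_draws) < reliability, nrow = n_units)
    background <- matrix(runif(n_units * n_draws) < b, nrow = n_units)
    via_group | background
  })
}

# Partition n fibres into consecutive groups of `size` (remainder becomes a
# smaller trailing group).
make_groups <- function(n, size) {
  if (size <= 1L) return(seq_len(n))
  rep(seq_len(ceiling(n / size)), each = size)[seq_len(n)]
}

#' Simulate a multi-field-of-view population experiment
#'
#' Emulates the population design: many fields of view (FOVs), each with
#' 4-21 labelled fibres at known positions, a subset of which respond to
#' the repeated sensory stimulus. Responsiveness and trial-to-trial
#' variability both flow through [simulate_correlated_binary()]:
#'
#' * Fibre level: shared-driver groups of `coupling$group_size` fibres are
#'   recruited together; the drive probability is set to
#'   `p_response / reliability` (no background), so the marginal per-fibre
#'   responsiveness equals `p_response` while responsive fibres co-occur in
#'   groups. `group_size = 1` gives independent activation.
#' * Trial level: responsive fibres of the same group share a per-trial
#'   driver with reliability `coupling$reliability` and marginal per-trial
#'   response probability `coupling$trial_reliability`; non-responsive
#'   fibres never respond.
#'
#' When `clustered_responders = TRUE`, the fibres of each co-driven group
#' are placed near a common parent (Thomas displacement with
#' `cluster_params$sigma_um`), so co-active fibres are also spatially
#' clustered; otherwise positions follow `config$pattern_kind`.
#'
#' @param config a [simulation_config()].
#' @param n_fov number of fields of view (default 85).
#' @param clustered_responders place same-group fibres near a shared parent.
#' @param seed optional seed overriding `config$seed`.
#' @return list of class `pf_population_sim` with elements `fovs` (each a
#'   list with `pattern`, `responsive`, `raster`, `groups`, `fov_id`) and
#'   `truth` (per-FOV group assignments and responsive flags, plus the
#'   config).
#' @export
simulate_population_experiment <- function(config, n_fov = 85,
                                           clustered_responders = FALSE,
                                           seed = config$seed) {
  stopifnot(inherits(config, "pf_sim_config"))
  region <- config_region(config)
  cpl <- config$coupling
  p_drive_fibre <- if (cpl$group_size > 1) {
    config$p_response / cpl$reliability
  } else {
    config$p_response
  }
  if (p_drive_fibre > 1) {
    stop_pf("p_response / reliability > 1: fibre-level drive not achievable")
  }
  rel_fibre <- if (cpl$group_size > 1) cpl$reliability else 1
  p_drive_trial <- cpl$trial_reliability / cpl$reliability
  if (p_drive_trial > 1) {
    stop_pf("trial_reliability / reliability > 1: trial drive not achievable")
  }
  with_seed(seed, {
    fovs <- vector("list", n_fov)
    for (i in seq_len(n_fov)) {
      n_i <- if (length(config$n_fibres_per_fov) > 1L) {
        sample(config$n_fibres_per_fov, 1L)
      } else {
        config$n_fibres_per_fov
      }
      groups <- make_groups(n_i, cpl$group_size)
      responsive <- drop(simulate_correlated_binary(
        groups, 1L, p_drive_fibre, rel_fibre, config$p_response))
      if (clustered_responders) {
        px <- runif(max(groups), region[1], region[1] + region[3])
        py <- runif(max(groups), region[2], region[2] + region[4])
        sig <- config$cluster_params$sigma_um
        x <- y <- numeric(n_i)
        for (k in seq_len(n_i)) {
          repeat {
            cx <- px[groups[k]] + rnorm(1L, 0, sig)
            cy <- py[groups[k]] + rnorm(1L, 0, sig)
            if (cx >= region[1] && cx <= region[1] + region[3] &&
                cy >= region[2] && cy <= region[2] + region[4]) break
          }
          x[k] <- cx
          y[k] <- cy
        }
        pattern <- pf_pattern(x, y, region)
      } else {
        pattern <- simulate_point_pattern(config, n = n_i, seed = NULL)$pattern
      }
      raster <- matrix(FALSE, nrow = n_i, ncol = config$n_trials)
      if (any(responsive)) {
        raster[responsive, ] <- simulate_correlated_binary(
          groups[responsive], config$n_trials, p_drive_trial,
          cpl$reliability, cpl$trial_reliability)
      }
      stim_times <- seq_len(config$n_trials) * config$stimulus_interval_s
      fovs[[i]] <- list(
        pattern = pf_pattern(pattern$x, pattern$y, region,
                             labels = ifelse(responsive, "responding",
                                             "labelled")),
        responsive = responsive,
        raster = pf_raster(raster, stimulus_times = stim_times, fov_id = i),
        groups = groups,
        fov_id = i)
    }
    structure(list(
      fovs = fovs,
      truth = list(config = config,
                   groups = lapply(fovs, `[[`, "groups"),
                   responsive = lapply(fovs, `[[`, "responsive"))
    ), class = "pf_population_sim")
  })
}

#' Observed responder counts per field of view
#'
#' @param sim a `pf_population_sim` (or a list of FOV lists with a
#'   `responsive` element).
#' @return integer vector, number of responsive fibres per FOV.
#' @export
responder_counts <- function(sim) {
  fovs <- if (inherits(sim, "pf_population_sim")) sim$fovs else sim
  vapply(fovs, function(f) sum(f$responsive), integer(1))
}

#' Labelled-fibre counts per field of view
#'
#' @param sim a `pf_population_sim`.
#' @return integer vector of fibre counts per FOV.
#' @export
labelled_counts <- function(sim) {
  fovs <- if (inherits(sim, "pf_population_sim")) sim$fovs else sim
  vapply(fovs, function(f) length(f$responsive), integer(1))
}
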