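#' Simulate a spatial point pattern with known structure
#'
#' Generates fibre cross-section positions under one of three generative
#' regimes:
#'
#' * `csr`: points i.i.d. uniform on the region (complete spatial
#'   randomness).
#' * `regular`: a square lattice jittered uniformly by a fraction of its
#'   spacing, emulating a tendency towards regular spacing.
#' * `thomas_cluster`: a Thomas cluster process with a fixed number of
#'   uniformly placed parents, each with a fixed number of offspring
#'   displaced by an isotropic Gaussian of s.d. `sigma_um`. Offspring
#'   falling outside the region are redrawn from the same parent, keeping
#'   the point count exact; this slightly biases offspring of edge parents
#'   inwards (documented edge bias).
#'
#' @param config a [simulation_config()]; `pattern_kind`, `cluster_params`,
#'   `regular_jitter_frac`, the region and (for csr/regular)
#'   `n_fibres_per_fov` are used. If `n_fibres_per_fov` is a range, one
#'   value is sampled.
#' @param n optional explicit point count (csr/regular), overriding the
#'   config.
#' @param seed optional seed overriding `config$seed`.
#'
#' @return list with `pattern` (a [pf_pattern()]) and `truth` (a list with
#'   the true `pattern_kind` and, for cluster patterns, `parent_id` and
#'   parent positions).
#' @examples
#' sim <- simulate_point_pattern(simulation_config(seed = 1,
#'   pattern_kind = "thomas_cluster"))
#' mean_nn_distance(sim$pattern)
#' @export
simulate_point_pattern <- function(config, n = NULL, seed = config$seed) {
  stopifnot(inherits(config, "pf_sim_config"))
  region <- config_region(config)
  with_seed(seed, {
    if (config$pattern_kind == "thomas_cluster") {
      cp <- config$cluster_params
      res <- rthomas_exact(cp$n_parents, cp$offspring_per_parent,
                           cp$sigma_um, region)
      truth <- list(pattern_kind = "thomas_cluster",
                    parent_id = res$parent_id,
                    parent_x = res$parent_x, parent_y = res$parent_y)
      pattern <- pf_pattern(res$x, res$y, region)
    } else {
      if (is.null(n)) {
        n <- if (length(config$n_fibres_per_fov) > 1L) {
          sample(config$n_fibres_per_fov, 1L)
        } else {
          config$n_fibres_per_fov
        }
      }
      if (config$pattern_kind == "csr") {
        pattern <- pf_pattern(runif(n, region[1], region[1] + region[3]),
                              runif(n, region[2], region[2] + region[4]),
                              region)
      } else {
        pattern <- rregular(n, region, config$regular_jitter_frac)
      }
      truth <- list(pattern_kind = config$pattern_kind)
    }
    list(pattern = pattern, truth = truth)
  })
}

# Thomas process with exact counts: n_parents uniform parents, each with
# `offspring` children displaced by N(0, sigma^2) per axis; children outside
# the region are resampled from the same parent.
rthomas_exact <- function(n_parents, offspring, sigma, region,
                          max_tries = 1000L) {
  if (sigma <= 0) stop_pf("Thomas dispersion sigma must be > 0")
  if (region[3] <= 0 || region[4] <= 0) stop_pf("region area must be > 0")
  px <- runif(n_parents, region[1], region[1] + region[3])
  py <- runif(n_parents, region[2], region[2] + region[4])
  n <- n_parents * offspring
  x <- y <- numeric(n)
  parent_id <- rep(seq_len(n_parents), each = offspring)
  for (k in seq_len(n)) {
    p <- parent_id[k]
    for (try in seq_len(max_tries)) {
      cx <- px[p] + rnorm(1L, 0, sigma)
      cy <- py[p] + rnorm(1L, 0, sigma)
      if (cx >= region[1] && cx <= region[1] + region[3] &&
          cy >= region[2] && cy <= region[2] + region[4]) break
      if (try == max_tries) stop_pf("failed to place offspring inside region")
    }
    x[k] <- cx
    y[k] <- cy
  }
  list(x = x, y = y, parent_id = parent_id, parent_x = px, parent_y = py)
}

# Jittered square lattice with ~n points. The lattice spacing is chosen so
# that an nx-by-ny grid (nx*ny >= n) fits inside the region; the first n
# lattice sites (row-major) are kept and jittered uniformly by
# +/- jitter_frac * spacing / 2 per axis (clamped to the region).
rregular <- function(n, region, jitter_frac = 0.1) {
  if (n == 0L) return(pf_pattern(numeric(0), numeric(0), region))
  aspect <- region[3] / region[4]
  nx <- max(1L, round(sqrt(n * aspect)))
  ny <- ceiling(n / nx)
  # density cap: spacing must stay positive
  if (nx > region[3] * 1e6 || ny > region[4] * 1e6) {
    stop_pf("requested n exceeds the density cap for a regular pattern")
  }
  gx <- region[1] + (seq_len(nx) - 0.5) * region[3] / nx
  gy <- region[2] + (seq_len(ny) - 0.5) * region[4] / ny
  sites <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  spacing <- min(region[3] / nx, region[4] / ny)
  jit <- jitter_frac * spacing / 2
  x <- pmin(pmax(sites$x + runif(n, -jit, jit), region[1]),
            region[1] + region[3])
  y <- pmin(pmax(sites$y + runif(n, -jit, jit), region[2]),
            region[2] + region[4])
  pf_pattern(x, y, region)
}

#' Simulate a bouton map at a known labelled fraction
#'
#' Forward model inverted by [estimate_labelled_fraction()]: in a thin
#' section extending `section_thickness_um` along the fibre axis, a fibre
#' contributes a bouton with probability `section_thickness / bouton
#' spacing`, so the expected bouton count is
#' `labelled_fraction * pf_density * area * thickness / spacing`.
#' The realised count is Poisson with that mean and positions are uniform.
#' Sections thicker than the bouton spacing would contain multiple boutons
#' per fibre and are not supported.
#'
#' @param true_labelled_fraction fraction of parallel fibres labelled.
#' @param params a [density_params()].
#' @param region numeric `c(x0, y0, width, height)` in um.
#' @param seed optional seed.
#' @return list with `pattern` (bouton positions) and `truth` (the labelled
#'   fraction and expected count).
#' @examples
#' m <- simulate_bouton_map(0.0038, density_params(), c(0, 0, 100, 100),
#'                          seed = 1)
#' m$truth$expected_count # ~56.5
#' @export
simulate_bouton_map <- function(true_labelled_fraction, params = density_params(),
                                region, seed = NULL) {
  check_probability(true_labelled_fraction, "true_labelled_fraction")
  stopifnot(inherits(params, "pf_density_params"))
  if (params$section_thickness_um > params$bouton_spacing_um) {
    stop_pf("section thickness > bouton spacing is not supported ",
            "(a fibre could contribute several boutons per section)")
  }
  region <- as.numeric(region)
  if (region[3] <= 0 || region[4] <= 0) stop_pf("region area must be > 0")
  expected <- true_labelled_fraction * params$pf_density_per_um2 *
    region_area(region) * params$section_thickness_um /
    params$bouton_spacing_um
  with_seed(seed, {
    n <- rpois(1L, expected)
    pattern <- pf_pattern(runif(n, region[1], region[1] + region[3]),
                          runif(n, region[2], region[2] + region[4]),
                          region)
    list(pattern = pattern,
         truth = list(labelled_fraction = true_labelled_fraction,
                      expected_count = expected))
  })
}
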