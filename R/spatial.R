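#' Mean nearest-neighbour distance of a point pattern
#'
#' The test statistic of the spatial randomness test: the mean, over all
#' points, of the Euclidean distance to the nearest other point. No edge
#' correction is applied; the Monte Carlo null is simulated in the identical
#' bounded region, so edge effects affect observed and null values alike and
#' cancel by construction.
#'
#' @param p a [pf_pattern()] with at least 2 points.
#' @return Mean nearest-neighbour distance in um.
#' @examples
#' p <- pf_pattern(c(0, 7), c(0, 0), region = c(0, 0, 10, 10))
#' mean_nn_distance(p) # 7
#' @export
mean_nn_distance <- function(p) {
  stopifnot(inherits(p, "pf_pattern"))
  n <- length(p$x)
  if (n < 2L) stop_pf("mean_nn_distance() needs at least 2 points")
  d <- as.matrix(stats::dist(cbind(p$x, p$y)))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

# Mean NND for many uniform (CSR) patterns at once.
# Returns a vector of length n_rep; each replicate has `n` points i.i.d.
# uniform in `region`. Vectorised over replicates: for each unordered pair
# (i, j) the distance is computed for all replicates simultaneously and the
# per-point running minimum updated, so cost is O(n^2) vector operations.
csr_mean_nnd_replicates <- function(n, region, n_rep) {
  xs <- matrix(runif(n_rep * n, region[1], region[1] + region[3]),
               nrow = n_rep)
  ys <- matrix(runif(n_rep * n, region[2], region[2] + region[4]),
               nrow = n_rep)
  nn <- matrix(Inf, nrow = n_rep, ncol = n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- sqrt((xs[, i] - xs[, j])^2 + (ys[, i] - ys[, j])^2)
      nn[, i] <- pmin(nn[, i], dij)
      nn[, j] <- pmin(nn[, j], dij)
    }
  }
  rowMeans(nn)
}

#' Monte Carlo test of complete spatial randomness (CSR)
#'
#' Tests whether a point pattern deviates from complete spatial randomness
#' using the mean nearest-neighbour distance (NND). `n_replicates` uniform
#' patterns with the same number of points are simulated in the same region;
#' the observed mean NND is ranked within the null distribution. Shorter
#' distances than expected indicate clustering, longer distances regular
#' spacing.
#'
#' The two-sided p-value uses the add-one convention:
#' `p = 2 * min(r_low + 1, r_high + 1) / (n_replicates + 1)`, capped at 1,
#' where `r_low`/`r_high` count replicates with mean NND less/greater than
#' or equal to the observed value. This keeps p > 0 for any finite number of
#' replicates.
#'
#' @param p a [pf_pattern()] with at least 3 points.
#' @param n_replicates number of uniform replicates (default 10000).
#' @param seed optional integer; if given, the test is reproducible and the
#'   caller's RNG stream is left untouched.
#' @param region optional override of the pattern's region (e.g. from
#'   [region_convention()]).
#' @return An object of class `pf_csr_test`: list with `observed_mean_nnd`,
#'   `null_mean`, `null_quantiles`, `n_points`, `n_replicates`, `direction`
#'   (`"clustered"` iff observed < null median, else `"regular"`),
#'   `p_value` (two-sided) and `seed`.
#' @examples
#' p <- simulate_point_pattern(simulation_config(seed = 1, n_fibres_per_fov = 15))
#' csr_monte_carlo_test(p$pattern, n_replicates = 999, seed = 1)
#' @export
csr_monte_carlo_test <- function(p, n_replicates = 10000L, seed = NULL,
                                 region = NULL) {
  stopifnot(inherits(p, "pf_pattern"))
  n <- length(p$x)
  if (n < 3L) stop_pf("csr_monte_carlo_test() needs at least 3 points")
  check_number(n_replicates, "n_replicates", positive = TRUE)
  region <- if (is.null(region)) p$region else as.numeric(region)
  if (length(region) != 4L || region[3] <= 0 || region[4] <= 0) {
    stop_pf("degenerate region")
  }
  obs <- mean_nn_distance(p)
  null <- with_seed(seed, csr_mean_nnd_replicates(n, region, n_replicates))
  r_low <- sum(null <= obs)
  r_high <- sum(null >= obs)
  p_val <- min(1, 2 * min(r_low + 1, r_high + 1) / (n_replicates + 1))
  structure(list(
    observed_mean_nnd = obs,
    null_mean = mean(null),
    null_quantiles = quantile(null, c(0.025, 0.5, 0.975)),
    n_points = n,
    n_replicates = as.integer(n_replicates),
    direction = if (obs < median(null)) "clustered" else "regular",
    p_value = p_val,
    region = region,
    seed = seed
  ), class = "pf_csr_test")
}

#' @export
print.pf_csr_test <- function(x, ...) {
  cat("Monte Carlo test of complete spatial randomness (mean NND)\n")
  cat(sprintf("  n = %d points, %d replicates\n", x$n_points, x$n_replicates))
  cat(sprintf("  observed mean NND = %.3f um; null mean = %.3f um\n",
              x$observed_mean_nnd, x$null_mean))
  cat(sprintf("  direction: %s; two-sided p = %.4g\n", x$direction, x$p_value))
  invisible(x)
}

#' Observation-region conventions for the CSR test
#'
#' Builds the rectangular test region: for in vivo data, the stained and
#' imaged area is approximated by the bounding rectangle of the points (or
#' the pattern's own region); for slice anatomy, the bounding width of the
#' labelled fibres multiplied by the molecular-layer thickness. An area
#' multiplier > 1 (aspect ratio preserved) reproduces the doubled-area
#' robustness check: a genuinely clustered pattern stays significant when
#' the assumed region is enlarged, whereas regular spacing may not.
#'
#' @param p a [pf_pattern()].
#' @param mode `"in_vivo"` (bounding rectangle / recorded region) or
#'   `"slice"` (bounding width x molecular-layer thickness).
#' @param ml_thickness_um molecular-layer thickness in um (slice mode only).
#' @param area_multiplier scale the area by this factor about the region
#'   centre, preserving aspect ratio.
#' @param use_pattern_region in vivo mode: use the pattern's stored region
#'   (default) rather than the bounding rectangle of the points.
#' @return numeric `c(x0, y0, width, height)`.
#' @export
region_convention <- function(p, mode = c("in_vivo", "slice"),
                              ml_thickness_um = NULL, area_multiplier = 1,
                              use_pattern_region = TRUE) {
  stopifnot(inherits(p, "pf_pattern"))
  mode <- match.arg(mode)
  check_number(area_multiplier, "area_multiplier", positive = TRUE)
  if (mode == "slice") {
    if (is.null(ml_thickness_um)) {
      stop_pf("slice mode needs `ml_thickness_um` (molecular-layer thickness)")
    }
    check_number(ml_thickness_um, "ml_thickness_um", positive = TRUE)
    width <- diff(range(p$x))
    if (width <= 0) stop_pf("bounding width of points is zero")
    region <- c(min(p$x), min(p$y), width, ml_thickness_um)
  } else if (use_pattern_region) {
    region <- p$region
  } else {
    region <- c(min(p$x), min(p$y), diff(range(p$x)), diff(range(p$y)))
    if (region[3] <= 0 || region[4] <= 0) stop_pf("degenerate bounding box")
  }
  if (area_multiplier != 1) {
    s <- sqrt(area_multiplier)
    cx <- region[1] + region[3] / 2
    cy <- region[2] + region[4] / 2
    region <- c(cx - s * region[3] / 2, cy - s * region[4] / 2,
                s * region[3], s * region[4])
  }
  region
}

#' Stitch several fields of view into one activity map
#'
#' Translates each field of view (FOV) by its recorded offset into a common
#' molecular-layer coordinate frame and concatenates the points. Fibres
#' appearing in two abutting FOVs are merged when closer than `tol_um`
#' (default 1 um, below inter-fibre distances of interest): of any group of
#' mutually-near duplicates the first occurrence is kept.
#'
#' @param fovs list of [pf_pattern()] objects in FOV-local coordinates.
#' @param offsets matrix/data.frame with columns `x`, `y` (um), one row per
#'   FOV: position of each FOV's origin in the map frame.
#' @param tol_um duplicate-merge tolerance in um.
#' @return A [pf_pattern()] covering the bounding region of all FOVs.
#' @export
stitch_activity_map <- function(fovs, offsets, tol_um = 1) {
  stopifnot(is.list(fovs), length(fovs) >= 1L)
  offsets <- as.matrix(offsets)
  if (nrow(offsets) != length(fovs) || ncol(offsets) < 2L) {
    stop_pf("`offsets` must have one (x, y) row per FOV")
  }
  xs <- ys <- numeric(0)
  labs <- character(0)
  have_labels <- !any(vapply(fovs, function(f) is.null(f$labels), logical(1)))
  rx0 <- ry0 <- Inf
  rx1 <- ry1 <- -Inf
  for (i in seq_along(fovs)) {
    f <- fovs[[i]]
    stopifnot(inherits(f, "pf_pattern"))
    xs <- c(xs, f$x + offsets[i, 1])
    ys <- c(ys, f$y + offsets[i, 2])
    if (have_labels) labs <- c(labs, f$labels)
    rx0 <- min(rx0, f$region[1] + offsets[i, 1])
    ry0 <- min(ry0, f$region[2] + offsets[i, 2])
    rx1 <- max(rx1, f$region[1] + f$region[3] + offsets[i, 1])
    ry1 <- max(ry1, f$region[2] + f$region[4] + offsets[i, 2])
  }
  keep <- rep(TRUE, length(xs))
  if (length(xs) >= 2L && tol_um > 0) {
    d <- as.matrix(stats::dist(cbind(xs, ys)))
    for (i in seq_along(xs)[-1L]) {
      if (any(d[i, seq_len(i - 1L)][keep[seq_len(i - 1L)]] < tol_um)) {
        keep[i] <- FALSE
      }
    }
  }
  pf_pattern(xs[keep], ys[keep], region = c(rx0, ry0, rx1 - rx0, ry1 - ry0),
             labels = if (have_labels) labs[keep])
}
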