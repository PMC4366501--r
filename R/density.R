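#' Anatomical parameters for labelling-density calibration
#'
#' @param bouton_spacing_um mean distance between two boutons on the same
#'   fibre (default 3.7 um).
#' @param pf_density_per_um2 packing density of parallel fibres in the
#'   molecular-layer cross-section (default 5.5 per um^2, the midpoint of
#'   the published 5-6 range).
#' @param pfs_per_pc number of parallel fibres crossing one Purkinje cell
#'   dendritic tree (default 150000).
#' @param pc_width_um width of the Purkinje cell dendritic tree
#'   (default 200 um).
#' @param section_thickness_um extent of the analysed section along the
#'   fibre axis (default 1 um).
#' @return list of class `pf_density_params`.
#' @export
density_params <- function(bouton_spacing_um = 3.7,
                           pf_density_per_um2 = 5.5,
                           pfs_per_pc = 150000,
                           pc_width_um = 200,
                           section_thickness_um = 1) {
  for (nm in c("bouton_spacing_um", "pf_density_per_um2", "pfs_per_pc",
               "pc_width_um", "section_thickness_um")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  structure(list(bouton_spacing_um = bouton_spacing_um,
                 pf_density_per_um2 = pf_density_per_um2,
                 pfs_per_pc = pfs_per_pc,
                 pc_width_um = pc_width_um,
                 section_thickness_um = section_thickness_um),
            class = "pf_density_params")
}

#' Estimate the labelled fraction of parallel fibres from a bouton map
#'
#' In a section extending `section_thickness_um` along the fibre axis, each
#' labelled fibre contributes on average `thickness / bouton spacing`
#' boutons. The bouton density (count / area) multiplied by
#' `bouton_spacing / thickness` therefore estimates the areal density of
#' labelled fibres, and dividing by the known packing density of parallel
#' fibres gives the labelled fraction.
#'
#' @param bouton_map a [pf_pattern()] of bouton positions.
#' @param params a [density_params()]; section thickness must not exceed
#'   the bouton spacing.
#' @return list with `fraction`, `bouton_density_per_um2`,
#'   `fibre_density_per_um2` and `n_boutons`. An empty map returns fraction
#'   0 with a warning; a fraction >= 1 (implausible labelling) is an error.
#' @examples
#' m <- simulate_bouton_map(0.0038, density_params(), c(0, 0, 100, 100),
#'                          seed = 1)
#' estimate_labelled_fraction(m$pattern)$fraction
#' @export
estimate_labelled_fraction <- function(bouton_map, params = density_params()) {
  stopifnot(inherits(bouton_map, "pf_pattern"),
            inherits(params, "pf_density_params"))
  if (params$section_thickness_um > params$bouton_spacing_um) {
    stop_pf("section thickness > bouton spacing is not supported")
  }
  n <- length(bouton_map$x)
  area <- region_area(bouton_map$region)
  bouton_density <- n / area
  fibre_density <- bouton_density * params$bouton_spacing_um /
    params$section_thickness_um
  fraction <- fibre_density / params$pf_density_per_um2
  if (n == 0L) {
    warning("empty bouton map: labelled fraction estimated as 0",
            call. = FALSE)
  }
  if (fraction >= 1) {
    stop_pf(sprintf("estimated labelled fraction %.3g >= 1: implausible ",
                    fraction), "labelling density")
  }
  list(fraction = fraction, bouton_density_per_um2 = bouton_density,
       fibre_density_per_um2 = fibre_density, n_boutons = n)
}

#' Expected number of labelled parallel fibres per Purkinje cell
#'
#' `labelled fraction x fibres per Purkinje cell`, rounded to the nearest
#' integer (e.g. a fraction of 0.0038 of 150000 fibres gives 570).
#'
#' @param fraction labelled fraction in `[0, 1)`.
#' @param params a [density_params()].
#' @return integer count.
#' @examples
#' expected_pf_count_per_pc(0.0038) # 570
#' @export
expected_pf_count_per_pc <- function(fraction, params = density_params()) {
  check_number(fraction, "fraction", min = 0)
  if (fraction >= 1) stop_pf("`fraction` must be < 1")
  as.integer(round(fraction * params$pfs_per_pc))
}

#' Plausibility check of observed labelled-fibre counts
#'
#' One-sample two-sided t-test of independently observed labelled-fibre
#' counts (e.g. direct counts within Purkinje-cell-tree-sized areas across
#' animals) against the expectation derived from the density calibration.
#'
#' @param observed_counts numeric vector (>= 2 values, non-zero variance).
#' @param expected expected count.
#' @return list with `t`, `df`, `p_value`, `mean_observed`, `expected`.
#' @export
plausibility_check <- function(observed_counts, expected) {
  if (length(observed_counts) < 2L) stop_pf("need >= 2 observations")
  if (var(observed_counts) == 0) {
    stop_pf("zero variance in observed counts")
  }
  tt <- t.test(observed_counts, mu = expected)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_observed = mean(observed_counts),
       expected = expected)
}
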