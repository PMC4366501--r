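#' Trial-to-trial coupling of one fibre pair
#'
#' Pearson's correlation between the two fibres' binary response sequences
#' over repeated stimulus presentations. The two-sided p-value of the
#' correlation is the pair's "probability of independence": below 0.05 the
#' pair is considered significantly coupled. On binary data the Pearson
#' coefficient equals the phi coefficient of the 2x2 contingency table.
#'
#' If either fibre responded on every trial or on none, the correlation is
#' undefined; the pair is flagged `indeterminate` and excluded from
#' coupled-fraction denominators rather than counted as independent.
#'
#' @param x,y logical/0-1 response vectors over the same trials.
#' @param method `"t"` (default): p from the t-distribution on `n - 2`
#'   degrees of freedom, the common large-sample practice;
#'   `"permutation"`: exact-style p from seeded random shuffles of one row,
#'   `(1 + #{|r*| >= |r|}) / (n_perm + 1)` — preferable when trials are few.
#' @param n_perm number of shuffles for the permutation method.
#' @param seed seed for the permutation method.
#' @param distance_um optional pair distance, carried through to the result.
#' @return list of class `pf_coupling`: `r`, `p_independence`, `coupled`
#'   (p < 0.05), `indeterminate`, `n_trials`, `distance_um`.
#' @export
pair_coupling <- function(x, y, method = c("t", "permutation"),
                          n_perm = 10000L, seed = NULL, distance_um = NA) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop_pf("mismatched trial counts")
  n <- length(x)
  if (n < 3L) stop_pf("need at least 3 trials")
  if (var(x) == 0 || var(y) == 0) {
    return(structure(list(r = NA_real_, p_independence = NA_real_,
                          coupled = NA, indeterminate = TRUE, n_trials = n,
                          distance_um = distance_um),
                     class = "pf_coupling"))
  }
  r <- cor(x, y)
  if (method == "t") {
    p <- cor.test(x, y, method = "pearson",
                  alternative = "two.sided")$p.value
  } else {
    p <- with_seed(seed, {
      r_perm <- vapply(seq_len(n_perm), function(i) cor(x, sample(y)),
                       numeric(1))
      (1 + sum(abs(r_perm) >= abs(r) - 1e-12)) / (n_perm + 1)
    })
  }
  structure(list(r = r, p_independence = p, coupled = p < 0.05,
                 indeterminate = FALSE, n_trials = n,
                 distance_um = distance_um),
            class = "pf_coupling")
}

#' Coupling results for all within-FOV fibre pairs
#'
#' Applies [pair_coupling()] to every pair of co-active (responsive) fibres
#' simultaneously imaged in the same field of view — the analysis is
#' restricted to within-FOV pairs because only those share trials.
#'
#' @param fovs list of FOV entries (`pattern`, `responsive`, `raster`), as
#'   produced by [simulate_population_experiment()], or a
#'   `pf_population_sim`.
#' @param which `"responsive"` (default: pairs of co-active fibres) or
#'   `"all"` (all labelled pairs).
#' @param ... passed to [pair_coupling()].
#' @return data.frame with one row per pair: `fov_id`, `i`, `j`, `r`,
#'   `p_independence`, `coupled`, `indeterminate`, `distance_um`.
#' @export
coupling_pairs <- function(fovs, which = c("responsive", "all"), ...) {
  if (inherits(fovs, "pf_population_sim")) fovs <- fovs$fovs
  which <- match.arg(which)
  rows <- list()
  for (f in fovs) {
    sel <- if (which == "responsive") which(f$responsive) else
      seq_along(f$responsive)
    if (length(sel) < 2L) next
    for (a in seq_along(sel)[-length(sel)]) {
      for (b in seq.int(a + 1L, length(sel))) {
        i <- sel[a]
        j <- sel[b]
        d <- sqrt((f$pattern$x[i] - f$pattern$x[j])^2 +
                    (f$pattern$y[i] - f$pattern$y[j])^2)
        pc <- pair_coupling(f$raster$responses[i, ], f$raster$responses[j, ],
                            distance_um = d, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          fov_id = f$fov_id, i = i, j = j, r = pc$r,
          p_independence = pc$p_independence, coupled = pc$coupled,
          indeterminate = pc$indeterminate, distance_um = d)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(fov_id = integer(0), i = integer(0), j = integer(0),
                      r = numeric(0), p_independence = numeric(0),
                      coupled = logical(0), indeterminate = logical(0),
                      distance_um = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Fraction of significantly coupled pairs
#'
#' `coupled / determinate`, with raw counts. Indeterminate pairs (a fibre
#' responding on none or all trials) are excluded from the denominator.
#'
#' @param pairs data.frame from [coupling_pairs()] (or any frame with
#'   `coupled` and `indeterminate` columns).
#' @return list with `fraction`, `n_coupled`, `n_determinate`, `n_total`.
#' @export
coupled_fraction <- function(pairs) {
  det <- !pairs$indeterminate
  if (!any(det)) stop_pf("zero determinate pairs")
  list(fraction = mean(pairs$coupled[det]),
       n_coupled = sum(pairs$coupled[det]),
       n_determinate = sum(det),
       n_total = nrow(pairs))
}

#' Independence probability versus pair distance
#'
#' Spearman rank correlation between each pair's probability of
#' independence and its spatial separation, plus a Mann-Whitney comparison
#' of the distances of coupled versus independent pairs. A positive
#' correlation (or a distance difference) would indicate that common-input
#' coupling is spatially organised within the field of view.
#'
#' @param pairs data.frame from [coupling_pairs()]; indeterminate pairs are
#'   dropped.
#' @return list with `spearman_rho`, `spearman_p`, `mw_p` (NA with fewer
#'   than one pair in either class), `n_coupled`, `n_independent`, and
#'   `flag` (`"ok"`, `"rho_undefined"`).
#' @export
independence_vs_distance <- function(pairs) {
  pairs <- pairs[!pairs$indeterminate, , drop = FALSE]
  if (!nrow(pairs)) stop_pf("no determinate pairs")
  if (!all(is.finite(pairs$distance_um))) {
    stop_pf("distances required for all pairs")
  }
  flag <- "ok"
  if (length(unique(pairs$distance_um)) < 2L ||
      length(unique(pairs$p_independence)) < 2L) {
    rho <- p_rho <- NA_real_
    flag <- "rho_undefined"
  } else {
    ct <- suppressWarnings(cor.test(pairs$p_independence, pairs$distance_um,
                                    method = "spearman"))
    rho <- unname(ct$estimate)
    p_rho <- ct$p.value
  }
  d_c <- pairs$distance_um[pairs$coupled]
  d_i <- pairs$distance_um[!pairs$coupled]
  mw_p <- if (length(d_c) >= 1L && length(d_i) >= 1L) {
    suppressWarnings(wilcox.test(d_c, d_i)$p.value)
  } else {
    NA_real_
  }
  list(spearman_rho = rho, spearman_p = p_rho, mw_p = mw_p,
       n_coupled = length(d_c), n_independent = length(d_i), flag = flag)
}

#' Are the non-coupled ("independent") pairs still clustered in space?
#'
#' Compares the distances of determinate-but-not-coupled pairs with the
#' distances of all labelled pairs from the same fields of view, reusing
#' [compare_distance_distributions()]. A significantly smaller median for
#' the independent pairs means spatial clustering of co-active fibres is
#' not explained by common-input coupling alone.
#'
#' @param pairs data.frame from [coupling_pairs()].
#' @param fovs the FOV list the pairs came from.
#' @return the [compare_distance_distributions()] result (`median_a` =
#'   independent pairs, `median_b` = all labelled pairs).
#' @export
independent_pair_clustering <- function(pairs, fovs) {
  pairs <- pairs[!pairs$indeterminate & !pairs$coupled, , drop = FALSE]
  if (!nrow(pairs)) stop_pf("no independent pairs")
  all_d <- coactive_pair_distances(fovs)$all
  if (!length(all_d)) stop_pf("no labelled pairs")
  compare_distance_distributions(pairs$distance_um, all_d)
}
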