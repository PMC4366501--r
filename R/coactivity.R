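#' Binomial null model for co-active fibre counts
#'
#' Under independent activation, the number of responding fibres in a field
#' of view with `n` labelled fibres is Binomial(`n`, `p_response`). This
#' builds the per-FOV mass functions and the pooled expected histogram of
#' responder counts (the sum of the per-FOV pmfs, i.e. the expected number
#' of FOVs containing k responding fibres).
#'
#' @param n_labelled integer vector, labelled fibres per FOV (all >= 1).
#' @param p_response per-fibre response probability. In the standard
#'   workflow this is estimated from the same dataset as the fraction of
#'   responder fibres among all labelled fibres (see
#'   [estimate_p_response()]); an externally known value can be supplied
#'   instead.
#' @return list of class `pf_coactivity_null`: `p_response`, `n_labelled`,
#'   `pmfs` (list of per-FOV pmfs over k = 0..n_i) and `expected_counts`
#'   (named vector over k = 0..max(n)).
#' @examples
#' null <- binomial_null(c(13, 13), 0.028)
#' null$pmfs[[1]][1] # (1 - 0.028)^13
#' @export
binomial_null <- function(n_labelled, p_response) {
  check_probability(p_response, "p_response")
  n_labelled <- as.integer(n_labelled)
  if (any(n_labelled < 1L)) stop_pf("all FOVs must have >= 1 labelled fibre")
  pmfs <- lapply(n_labelled, function(n) {
    setNames(dbinom(0:n, n, p_response), 0:n)
  })
  kmax <- max(n_labelled)
  expected <- numeric(kmax + 1L)
  for (pmf in pmfs) {
    expected[seq_along(pmf)] <- expected[seq_along(pmf)] + pmf
  }
  structure(list(p_response = p_response, n_labelled = n_labelled,
                 pmfs = pmfs,
                 expected_counts = setNames(expected, 0:kmax)),
            class = "pf_coactivity_null")
}

#' Estimate the per-fibre response probability from the data
#'
#' The fraction of responder fibres among all labelled fibres, pooled over
#' fields of view — the empirical plug-in for the binomial null.
#'
#' @param observed_counts responder count per FOV.
#' @param n_labelled labelled-fibre count per FOV.
#' @return scalar probability.
#' @export
estimate_p_response <- function(observed_counts, n_labelled) {
  if (length(observed_counts) != length(n_labelled)) {
    stop_pf("counts and n_labelled must align per FOV")
  }
  sum(observed_counts) / sum(n_labelled)
}

#' Chi-square test of observed co-active counts against the binomial null
#'
#' Compares the histogram of per-FOV responder counts with the pooled
#' binomial expectation. Tail bins are pooled (from the largest k downward)
#' until every expected count is at least `min_expected`; the statistic is
#' Pearson's X^2 over the remaining bins with `bins - 1` degrees of
#' freedom. Pooling stops at two bins. The default `min_expected = 1`
#' follows Cochran's minimum-expectation criterion and deliberately
#' preserves the sparse right tail, which carries the signal when co-active
#' counts shift upward.
#'
#' @param observed_counts integer vector, responder count per FOV (same
#'   FOV order as the null; the test is invariant to that order).
#' @param null a [binomial_null()].
#' @param min_expected pool tail bins until all expected counts reach this.
#' @return list of class `pf_coactivity_test`: `statistic`, `df`, `p_value`,
#'   and the pooled `observed`/`expected` tables.
#' @export
coactivity_test <- function(observed_counts, null, min_expected = 1) {
  stopifnot(inherits(null, "pf_coactivity_null"))
  observed_counts <- as.integer(observed_counts)
  if (length(observed_counts) != length(null$n_labelled)) {
    stop_pf("one observed count per FOV in the null is required")
  }
  if (any(observed_counts > null$n_labelled)) {
    stop_pf("observed count exceeds labelled fibres in some FOV")
  }
  expected <- null$expected_counts
  kmax <- length(expected) - 1L
  observed <- tabulate(observed_counts + 1L, nbins = kmax + 1L)
  while (length(expected) > 2L && expected[length(expected)] < min_expected) {
    n <- length(expected)
    expected[n - 1L] <- expected[n - 1L] + expected[n]
    observed[n - 1L] <- observed[n - 1L] + observed[n]
    expected <- expected[-n]
    observed <- observed[-n]
  }
  if (length(expected) < 2L) stop_pf("fewer than 2 bins after pooling")
  names(observed) <- names(expected)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(expected) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "pf_coactivity_test")
}

#' @export
print.pf_coactivity_test <- function(x, ...) {
  cat("Chi-square test of co-active fibre counts vs binomial null\n")
  cat(sprintf("  X^2 = %.3f, df = %d, p = %.4g\n", x$statistic, x$df,
              x$p_value))
  invisible(x)
}

#' Pairwise distances of co-active fibres and of all labelled fibres
#'
#' Euclidean distances in the sagittal plane, computed only within a field
#' of view. FOVs with at least two responders contribute active pairs;
#' every FOV with at least two labelled fibres contributes all-pairs.
#'
#' @param fovs list of FOV entries, each a list with `pattern` (a
#'   [pf_pattern()]) and `responsive` (logical per fibre) — the format
#'   produced by [simulate_population_experiment()].
#' @return list with numeric vectors `active` and `all` (um).
#' @export
coactive_pair_distances <- function(fovs) {
  if (inherits(fovs, "pf_population_sim")) fovs <- fovs$fovs
  active <- all_pairs <- numeric(0)
  for (f in fovs) {
    xy <- cbind(f$pattern$x, f$pattern$y)
    if (nrow(xy) >= 2L) all_pairs <- c(all_pairs, as.numeric(dist(xy)))
    act <- xy[f$responsive, , drop = FALSE]
    if (nrow(act) >= 2L) active <- c(active, as.numeric(dist(act)))
  }
  list(active = active, all = all_pairs)
}

#' Compare two distance distributions (Mann-Whitney)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with medians. The exact
#' null distribution is used when both samples have fewer than 50 values
#' and there are no ties; otherwise the normal approximation with tie
#' correction (the `stats::wilcox.test` switch point).
#'
#' @param a,b numeric samples (both non-empty).
#' @return list with `median_a`, `median_b`, `statistic` (U for sample `a`),
#'   `p_value`.
#' @export
compare_distance_distributions <- function(a, b) {
  if (!length(a) || !length(b)) stop_pf("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(median_a = median(a), median_b = median(b),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Bootstrap confidence envelope around an expected distance CDF
#'
#' The expected cumulative distribution of pair distances is the empirical
#' CDF of all labelled pairs. To judge whether the active-pair CDF deviates
#' more than sampling noise allows, subsets of size `n_active_pairs` are
#' resampled (with replacement) from the all-pairs distances and the
#' pointwise `(1-level)/2` and `1-(1-level)/2` quantiles of their CDFs form
#' the envelope.
#'
#' @param all_distances numeric vector of all labelled-pair distances.
#' @param n_active_pairs subset size (must not exceed the number of
#'   available pairs — mirrors the data situation).
#' @param n_boot number of resampled subsets (>= 10000 for 99.9% coverage).
#' @param level envelope coverage (default 0.999).
#' @param grid evaluation grid (um); default: the sorted unique distances.
#' @param seed optional seed.
#' @return list with `grid`, `expected_cdf`, `lower`, `upper`, `level`.
#' @export
distance_cdf_envelope <- function(all_distances, n_active_pairs,
                                  n_boot = 10000L, level = 0.999,
                                  grid = NULL, seed = NULL) {
  if (!length(all_distances)) stop_pf("no distances supplied")
  if (n_active_pairs > length(all_distances)) {
    stop_pf("n_active_pairs exceeds the number of available pairs")
  }
  if (n_boot < 10000L && level >= 0.999) {
    stop_pf("need n_boot >= 10000 for a 99.9% envelope")
  }
  if (is.null(grid)) grid <- sort(unique(all_distances))
  ec <- stats::ecdf(all_distances)
  expected_cdf <- ec(grid)
  alpha <- (1 - level) / 2
  cdfs <- with_seed(seed, {
    m <- matrix(sample(all_distances, n_boot * n_active_pairs,
                       replace = TRUE), nrow = n_boot)
    # per-replicate ECDF on the grid: count of values <= g, vectorised over
    # the grid by rowwise cumulative counting of bin membership
    t(apply(m, 1L, function(row) {
      stats::ecdf(row)(grid)
    }))
  })
  list(grid = grid, expected_cdf = expected_cdf,
       lower = apply(cdfs, 2L, quantile, probs = alpha, names = FALSE),
       upper = apply(cdfs, 2L, quantile, probs = 1 - alpha, names = FALSE),
       level = level)
}
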