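# shared fixtures and helpers, all generated in code

# Greedy matching of detected event onsets to ground-truth times within a
# tolerance; returns tp/fp/fn counts and matched onset errors (s).
match_events <- function(detected, truth, tol_s) {
  used <- rep(FALSE, length(detected))
  tp <- fn <- 0L
  errors <- numeric(0)
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(d) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
      errors <- c(errors, d[j])
    } else {
      fn <- fn + 1L
    }
  }
  list(tp = tp, fn = fn, fp = sum(!used), errors = errors)
}

# A small multi-FOV population with known responder flags and rasters,
# built directly (no generator), for deterministic co-activity tests.
toy_fov <- function(x, y, responsive, raster, fov_id = 1L,
                    region = c(0, 0, 56, 150)) {
  list(pattern = pf_pattern(x, y, region),
       responsive = responsive,
       raster = pf_raster(raster),
       groups = seq_along(x),
       fov_id = fov_id)
}

# brute-force mean nearest-neighbour distance (independent of the package
# implementation; plain double loop)
brute_mean_nnd <- function(x, y) {
  n <- length(x)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  mean(nn)
}
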