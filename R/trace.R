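#' Fluorescence trace of one region of interest
#'
#' One fibre's fluorescence time series, either raw fluorescence or dF/F,
#' with its sampling rate and any stimulus times.
#'
#' @param samples numeric vector of fluorescence samples.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param stimulus_times numeric vector of stimulus onset times in seconds
#'   (possibly empty); must be strictly increasing and within the trace.
#' @param units `"dff"` or `"raw"`.
#' @param roi_id optional identifier.
#' @return An object of class `pf_trace`.
#' @export
pf_trace <- function(samples, sampling_rate, stimulus_times = numeric(0),
                     units = c("dff", "raw"), roi_id = NULL) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  stimulus_times <- as.numeric(stimulus_times)
  duration <- length(samples) / sampling_rate
  if (length(stimulus_times)) {
    if (any(diff(stimulus_times) <= 0)) {
      stop_pf("stimulus times must be strictly increasing")
    }
    if (any(stimulus_times < 0) || any(stimulus_times > duration)) {
      stop_pf("stimulus times must lie within the trace duration")
    }
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 stimulus_times = stimulus_times, units = units,
                 roi_id = roi_id), class = "pf_trace")
}

#' @export
print.pf_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace (%s): %d samples at %g Hz (%.1f s), %d stimuli\n",
              x$units, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, length(x$stimulus_times)))
  invisible(x)
}

# time of sample i (0-based convention: first sample at t = 0)
sample_times <- function(trace) {
  (seq_along(trace$samples) - 1L) / trace$sampling_rate
}
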