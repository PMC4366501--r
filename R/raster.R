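#' Response raster: fibre x trial boolean matrix
#'
#' Stimulus-locked responses of all fibres of one field of view over
#' repeated stimulus presentations. All fibres share the same trial
#' sequence.
#'
#' @param responses logical (or 0/1) matrix, fibres in rows, trials in
#'   columns.
#' @param stimulus_times optional numeric vector of stimulus times (s), one
#'   per trial, strictly increasing.
#' @param fov_id optional identifier of the field of view.
#' @return An object of class `pf_raster`.
#' @export
pf_raster <- function(responses, stimulus_times = NULL, fov_id = NULL) {
  responses <- as.matrix(responses)
  if (ncol(responses) < 1L) stop_pf("raster needs at least 1 trial")
  if (is.numeric(responses)) {
    if (!all(responses %in% c(0, 1))) {
      stop_pf("raster entries must be logical or 0/1")
    }
    responses <- responses == 1
  }
  if (!is.logical(responses)) stop_pf("raster entries must be logical or 0/1")
  if (!is.null(stimulus_times)) {
    stimulus_times <- as.numeric(stimulus_times)
    if (length(stimulus_times) != ncol(responses)) {
      stop_pf("need one stimulus time per trial")
    }
    if (any(diff(stimulus_times) <= 0)) {
      stop_pf("stimulus times must be strictly increasing")
    }
  }
  structure(list(responses = responses, stimulus_times = stimulus_times,
                 fov_id = fov_id), class = "pf_raster")
}

#' @export
print.pf_raster <- function(x, ...) {
  cat(sprintf("Response raster: %d fibres x %d trials",
              nrow(x$responses), ncol(x$responses)))
  if (!is.null(x$fov_id)) cat(sprintf(" (FOV %s)", x$fov_id))
  cat(sprintf("; response rate %.3f\n", mean(x$responses)))
  invisible(x)
}

#' @export
dim.pf_raster <- function(x) dim(x$responses)
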