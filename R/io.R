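#' File contracts: traces, point patterns and rasters as CSV + JSON sidecar
#'
#' All tabular data are plain CSV; per-file metadata that does not fit a
#' column (sampling rate, stimulus times, region, units) lives in a JSON
#' sidecar at `<path>.json`. Round trips are lossless to full double
#' precision (values are written with 17 significant digits).
#'
#' * Traces: columns `time` (s, strictly increasing, uniform) and one
#'   `roi_<k>` column per fibre; sidecar: `sampling_rate`,
#'   `stimulus_times`, `units`.
#' * Point patterns: columns `x`, `y` (um) and optional `label`; sidecar:
#'   `region` = `[x0, y0, width, height]`.
#' * Rasters: column `fibre` (0-based id) plus `trial_<t>` 0/1 columns;
#'   sidecar: `stimulus_times`, `fov_id`.
#'
#' @param traces list of [pf_trace()] objects sharing sampling rate and
#'   stimulus times.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `read_*` return the package objects; `write_*` return `path`
#'   invisibly.
#' @name pf_io
NULL

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_pf(sprintf("missing sidecar file `%s`", sp))
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_pf(sprintf("`%s` is missing column(s): %s", path,
                    paste(missing, collapse = ", ")))
  }
}

write_num_csv <- function(df, path) {
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
}

#' @rdname pf_io
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "pf_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, logical(1), "pf_trace")))
  fs <- unique(vapply(traces, `[[`, numeric(1), "sampling_rate"))
  if (length(fs) != 1L) stop_pf("traces must share a sampling rate")
  ns <- unique(vapply(traces, function(t) length(t$samples), integer(1)))
  if (length(ns) != 1L) stop_pf("traces must share their length")
  units <- unique(vapply(traces, `[[`, character(1), "units"))
  if (length(units) != 1L) stop_pf("traces must share units")
  df <- data.frame(time = (seq_len(ns) - 1L) / fs)
  for (k in seq_along(traces)) df[[paste0("roi_", k)]] <- traces[[k]]$samples
  write_num_csv(df, path)
  write_sidecar(path, list(sampling_rate = fs,
                           stimulus_times = traces[[1]]$stimulus_times,
                           units = units))
  invisible(path)
}

#' @rdname pf_io
#' @export
read_traces <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  require_columns(df, "time", path)
  roi_cols <- grep("^roi_", names(df), value = TRUE)
  if (!length(roi_cols)) stop_pf(sprintf("`%s` has no roi_<k> columns", path))
  if (anyNA(df$time) || any(diff(df$time) <= 0)) {
    stop_pf(sprintf("`%s`: column `time` must be strictly increasing", path))
  }
  meta <- read_sidecar(path)
  stim <- as.numeric(meta$stimulus_times)
  lapply(seq_along(roi_cols), function(k) {
    x <- df[[roi_cols[k]]]
    if (anyNA(x)) {
      stop_pf(sprintf("`%s`: NA in column `%s`", path, roi_cols[k]))
    }
    pf_trace(x, meta$sampling_rate, stimulus_times = stim,
             units = meta$units, roi_id = k)
  })
}

#' @rdname pf_io
#' @param p a [pf_pattern()].
#' @export
write_points <- function(p, path) {
  stopifnot(inherits(p, "pf_pattern"))
  df <- as.data.frame(p)
  write_num_csv(df, path)
  write_sidecar(path, list(region = p$region))
  invisible(path)
}

#' @rdname pf_io
#' @export
read_points <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  require_columns(df, c("x", "y"), path)
  if (anyNA(df$x) || anyNA(df$y)) {
    stop_pf(sprintf("`%s`: NaN/NA in coordinate column(s)", path))
  }
  meta <- read_sidecar(path)
  pf_pattern(df$x, df$y, region = as.numeric(meta$region),
             labels = if ("label" %in% names(df)) df$label)
}

#' @rdname pf_io
#' @param raster a [pf_raster()].
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "pf_raster"))
  m <- raster$responses
  df <- data.frame(fibre = seq_len(nrow(m)) - 1L)
  for (t in seq_len(ncol(m))) df[[paste0("trial_", t)]] <- as.integer(m[, t])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  write_sidecar(path, list(stimulus_times = raster$stimulus_times,
                           fov_id = raster$fov_id))
  invisible(path)
}

#' @rdname pf_io
#' @export
read_raster <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  require_columns(df, "fibre", path)
  trial_cols <- grep("^trial_", names(df), value = TRUE)
  if (!length(trial_cols)) {
    stop_pf(sprintf("`%s` has no trial_<t> columns", path))
  }
  m <- as.matrix(df[, trial_cols, drop = FALSE])
  dimnames(m) <- NULL
  meta <- read_sidecar(path)
  stim <- if (is.null(meta$stimulus_times)) NULL else
    as.numeric(meta$stimulus_times)
  pf_raster(m == 1, stimulus_times = stim, fov_id = meta$fov_id)
}

#' Write an analysis report as JSON
#'
#' Serialises a (possibly nested) list of results to pretty-printed JSON
#' with full numeric precision.
#'
#' @param results a list.
#' @param path output file.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
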