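#' Planar point pattern in a bounded rectangular region
#'
#' Container for 2D coordinates of fibre cross-sections (or boutons) in the
#' sagittal plane, with an observation window and optional per-point labels
#' (e.g. `"responding"` vs `"labelled"`). Coordinates are micrometres in a
#' right-handed frame with the origin at the region's lower-left corner.
#'
#' @param x,y numeric vectors of equal length, coordinates in um.
#' @param region numeric vector `c(x0, y0, width, height)` in um; all points
#'   must lie inside (closed region) and the area must be positive.
#' @param labels optional character/factor vector, one label per point.
#'
#' @return An object of class `pf_pattern`: a list with elements `x`, `y`,
#'   `region` and `labels`.
#' @examples
#' p <- pf_pattern(c(10, 20), c(5, 5), region = c(0, 0, 56, 14))
#' npoints(p)
#' @export
pf_pattern <- function(x, y, region, labels = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop_pf("`x` and `y` must have equal length")
  if (anyNA(x) || anyNA(y)) stop_pf("NaN/NA in coordinates")
  region <- as.numeric(region)
  if (length(region) != 4L || anyNA(region)) {
    stop_pf("`region` must be c(x0, y0, width, height)")
  }
  if (region[3] <= 0 || region[4] <= 0) stop_pf("region area must be > 0")
  inside <- x >= region[1] & x <= region[1] + region[3] &
    y >= region[2] & y <= region[2] + region[4]
  if (!all(inside)) {
    stop_pf(sprintf("%d point(s) fall outside the region", sum(!inside)))
  }
  if (!is.null(labels)) {
    if (length(labels) != length(x)) {
      stop_pf("`labels` must have one entry per point")
    }
    labels <- as.character(labels)
  }
  structure(list(x = x, y = y, region = region, labels = labels),
            class = "pf_pattern")
}

#' @rdname pf_pattern
#' @param p a `pf_pattern`.
#' @export
npoints <- function(p) {
  stopifnot(inherits(p, "pf_pattern"))
  length(p$x)
}

#' @export
print.pf_pattern <- function(x, ...) {
  cat(sprintf("Planar point pattern: %d points\n", length(x$x)))
  cat(sprintf("Region: [%g, %g] x [%g, %g] um (area %g um^2)\n",
              x$region[1], x$region[1] + x$region[3],
              x$region[2], x$region[2] + x$region[4],
              x$region[3] * x$region[4]))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("Labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pf_pattern <- function(x, ...) {
  d <- data.frame(x = x$x, y = x$y)
  if (!is.null(x$labels)) d$label <- x$labels
  d
}

region_area <- function(region) region[3] * region[4]

#' Subset a point pattern by index or label
#'
#' @param p a [pf_pattern()].
#' @param which logical/integer index vector, or a single label string.
#' @return A `pf_pattern` with the selected points and the same region.
#' @export
subset_pattern <- function(p, which) {
  stopifnot(inherits(p, "pf_pattern"))
  if (is.character(which) && length(which) == 1L) {
    if (is.null(p$labels)) stop_pf("pattern has no labels to subset by")
    which <- p$labels == which
  }
  pf_pattern(p$x[which], p$y[which], p$region,
             labels = if (!is.null(p$labels)) p$labels[which])
}
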