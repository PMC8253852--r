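# Grid-based fallback segmentation: the B-scan is divided by n vertical
# lines, the user clicks one point per line, and a full-width boundary is
# interpolated/extrapolated through those points.

#' Vertical grid-line positions
#'
#' `n` equally spaced integer columns, the first at `floor(width/(2n))` and
#' subsequent ones `floor(width/n)` apart, so the lines sit at the centres
#' of `n` equal portions of the scan.
#'
#' @param width image width in pixels.
#' @param n number of lines (>= 2).
#' @return Integer vector of 0-based x positions.
#' @export
grid_lines <- function(width, n) {
  if (n < 2) .lw_stop("need at least 2 grid lines")
  if (width <= n) .lw_stop("width must exceed the number of grid lines")
  floor(width / (2 * n)) + floor(width / n) * (0:(n - 1L))
}

#' Interpolate a boundary through clicked grid points
#'
#' Shape-preserving (monotone Hermite) cubic interpolation through the
#' points on `[x_first, x_last]`, extended to the full image width by linear
#' extrapolation with the slope of the outermost segment. The curve passes
#' through every given point exactly and never overshoots the data range
#' between two consecutive points.
#'
#' @param points an open-mode [anchor_seq].
#' @param width image width; the result is defined on all columns.
#' @param label boundary label for the result.
#' @param height optional image height; extrapolated z is clipped to
#'   `[0, height-1]` (with a warning) when given.
#' @return An [oct_boundary] defined on every column.
#' @export
fit_boundary_from_points <- function(points, width, label = "ILM",
                                     height = NULL) {
  stopifnot(inherits(points, "anchor_seq"))
  if (points$mode != "open")
    .lw_stop("grid fitting needs open-mode anchors")
  if (anyDuplicated(points$x)) .lw_stop("duplicate x in grid points")
  x <- as.numeric(points$x); z <- as.numeric(points$z)
  n <- length(x)
  xi <- 0:(width - 1L)
  if (n == 2L) {
    slope <- (z[2L] - z[1L]) / (x[2L] - x[1L])
    zi <- z[1L] + slope * (xi - x[1L])
  } else {
    zi <- signal::pchip(x, z, pmin(pmax(xi, x[1L]), x[n]))
    # linear extrapolation with the end-segment secant slope
    sl_lo <- (z[2L] - z[1L]) / (x[2L] - x[1L])
    sl_hi <- (z[n] - z[n - 1L]) / (x[n] - x[n - 1L])
    zi[xi < x[1L]] <- z[1L] + sl_lo * (xi[xi < x[1L]] - x[1L])
    zi[xi > x[n]] <- z[n] + sl_hi * (xi[xi > x[n]] - x[n])
  }
  if (!is.null(height)) {
    out_of_range <- zi < 0 | zi > height - 1
    if (any(out_of_range))
      .lw_warn("extrapolated boundary clipped to image bounds on ",
               sum(out_of_range), " column(s)")
    zi <- pmin(pmax(zi, 0), height - 1)
  }
  oct_boundary(label, zi)
}
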