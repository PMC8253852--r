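#' B-scan image container
#'
#' A B-scan is stored as a numeric matrix of reflectivities in \[0, 1\] with
#' rows indexing depth (z, growing downward toward the choroid) and columns
#' indexing the lateral position (x, growing rightward). Coordinates used
#' throughout the package are 0-based: pixel (x = 0, z = 0) is the top-left
#' corner.
#'
#' @param pixels numeric matrix, intensities in \[0, 1\]; rows = depth.
#' @param scale_x,scale_z physical pixel pitch in mm/pixel.
#' @param id identifier used in CSV output (e.g. `"bscan_001"`).
#' @return An object of class `bscan` with fields `pixels`, `height`,
#'   `width`, `scale_x`, `scale_z`, `id`.
#' @export
bscan <- function(pixels, scale_x = NA_real_, scale_z = NA_real_,
                  id = "bscan") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    .lw_stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    .lw_stop("a B-scan needs at least 2x2 pixels")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    .lw_stop("B-scan intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    .lw_stop("B-scan intensities must lie in [0, 1]")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         scale_x = scale_x, scale_z = scale_z, id = as.character(id)),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan '%s': %d x %d px (depth x lateral)", x$id,
              x$height, x$width))
  if (is.finite(x$scale_x))
    cat(sprintf(", %.4g x %.4g mm/px", x$scale_x, x$scale_z))
  cat(">\n")
  invisible(x)
}

#' OCT volume container
#'
#' An ordered stack of B-scans sharing a common geometry.
#'
#' @param bscans list of [bscan] objects with identical height and width.
#' @param eye laterality: `"OD"`, `"OS"` or `"unknown"`.
#' @param source_format one of `"vol"`, `"images"`, `"container"`.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, eye = "unknown", source_format = "images") {
  if (!length(bscans)) .lw_stop("a volume needs at least one B-scan")
  if (!all(vapply(bscans, inherits, logical(1), "bscan")))
    .lw_stop("'bscans' must be a list of bscan objects")
  hs <- vapply(bscans, `[[`, numeric(1), "height")
  ws <- vapply(bscans, `[[`, numeric(1), "width")
  if (length(unique(hs)) != 1L || length(unique(ws)) != 1L)
    .lw_stop("all B-scans in a volume must share height and width")
  eye <- match.arg(eye, c("OD", "OS", "unknown"))
  source_format <- match.arg(source_format, c("vol", "images", "container"))
  structure(
    list(bscans = bscans, num_bscans = length(bscans), eye = eye,
         source_format = source_format),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  b <- x$bscans[[1L]]
  cat(sprintf("<oct_volume: %d B-scan(s) of %d x %d px, eye %s, from %s>\n",
              x$num_bscans, b$height, b$width, x$eye, x$source_format))
  invisible(x)
}

# clip + validate helper used by all readers
.as_unit_interval <- function(m) {
  m[!is.finite(m)] <- 0
  pmin(pmax(m, 0), 1)
}
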