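#' Cost image for live-wire tracing
#'
#' Wraps a strictly positive per-pixel traversal cost aligned with a B-scan.
#' Minimum-cost paths through this image follow dark (cheap) ridges, which
#' the preprocessing stage places on the boundary of interest.
#'
#' @param cost numeric matrix (rows = depth); all values must be `>= eps`.
#' @param eps positive cost floor.
#' @return An object of class `cost_image`.
#' @export
cost_image <- function(cost, eps = 1e-6) {
  if (!is.matrix(cost) || !is.numeric(cost))
    .lw_stop("'cost' must be a numeric matrix")
  if (eps <= 0) .lw_stop("'eps' must be positive")
  if (anyNA(cost) || any(!is.finite(cost)))
    .lw_stop("costs must be finite")
  if (min(cost) < eps)
    .lw_stop("all costs must be >= eps (", eps, ")")
  structure(list(cost = cost, eps = eps, height = nrow(cost),
                 width = ncol(cost)),
            class = "cost_image")
}

#' Edge weight between two neighbouring pixels
#'
#' The pixel graph is 8-connected and undirected; the weight of the edge
#' between pixels with costs `cost_a` and `cost_b` is their mean, scaled by
#' `sqrt(2)` for diagonal moves so that uniform-cost images yield Euclidean
#' path lengths.
#'
#' @param cost_a,cost_b strictly positive pixel costs.
#' @param diagonal logical; is the move diagonal?
#' @return The scalar edge weight.
#' @export
edge_weight <- function(cost_a, cost_b, diagonal = FALSE) {
  if (any(c(cost_a, cost_b) <= 0)) .lw_stop("pixel costs must be positive")
  ((cost_a + cost_b) / 2) * if (isTRUE(diagonal)) sqrt(2) else 1
}

.as_pixel_path <- function(x, z, total_cost) {
  structure(list(x = as.integer(x), z = as.integer(z),
                 total_cost = total_cost, n = length(x)),
            class = "pixel_path")
}

#' @export
print.pixel_path <- function(x, ...) {
  cat(sprintf("<pixel_path: %d pixels, total cost %.6g>\n", x$n,
              x$total_cost))
  invisible(x)
}

#' Minimum-cost path between two pixels
#'
#' Dijkstra shortest-path-first over the 8-connected pixel graph of a cost
#' image. Ties in the priority queue are broken by smaller (z, x), and the
#' predecessor is only updated on strict improvement, so results are
#' bit-reproducible.
#'
#' @param cost a [cost_image].
#' @param src,dst length-2 integer vectors `c(x, z)`, 0-based.
#' @param band optional `c(z_min, z_max)` restricting the search to a
#'   horizontal band of rows (used by [trace_boundary]).
#' @return A `pixel_path` with 0-based `x`, `z` and the exact `total_cost`.
#' @export
shortest_path <- function(cost, src, dst, band = NULL) {
  stopifnot(inherits(cost, "cost_image"))
  src <- as.integer(round(src)); dst <- as.integer(round(dst))
  inb <- function(p) p[1] >= 0 && p[1] <= cost$width - 1 &&
                     p[2] >= 0 && p[2] <= cost$height - 1
  if (!inb(src) || !inb(dst))
    .lw_stop("path endpoints outside the cost image")
  z0 <- 0L
  m <- cost$cost
  if (!is.null(band)) {
    z0 <- max(0L, as.integer(band[1L]))
    z1 <- min(cost$height - 1L, as.integer(band[2L]))
    z0 <- min(z0, src[2L], dst[2L])
    z1 <- max(z1, src[2L], dst[2L])
    m <- m[(z0 + 1L):(z1 + 1L), , drop = FALSE]
  }
  res <- .lw_dijkstra(m, src[2L] - z0, src[1L], dst[2L] - z0, dst[1L])
  .as_pixel_path(res$x, res$z + z0, res$total_cost)
}

#' Collapse a pixel path to a per-column boundary
#'
#' For every column the path visits, the boundary depth is the mean of the
#' visited z values in that column; columns not visited remain undefined.
#'
#' @param path a `pixel_path`.
#' @param width image width (number of columns of the owning B-scan).
#' @param label boundary label for the result.
#' @return An [oct_boundary] defined exactly on the visited columns.
#' @export
path_to_boundary <- function(path, width, label = "ILM") {
  stopifnot(inherits(path, "pixel_path"), path$n >= 1L)
  z <- rep(NA_real_, width)
  means <- tapply(path$z, path$x, mean)
  z[as.integer(names(means)) + 1L] <- as.numeric(means)
  oct_boundary(label, z)
}

#' Trace a layer boundary through anchor points
#'
#' Runs [shortest_path] between each pair of consecutive anchors, restricted
#' to a search band enclosing the two anchors padded vertically by
#' `band_pad` rows (full inter-anchor span horizontally), concatenates the
#' segments and collapses them to a per-column curve. Anchor columns are
#' pinned to their clicked depth exactly.
#'
#' @param cost a [cost_image].
#' @param anchors an open-mode [anchor_seq] inside the image.
#' @param label boundary label for the result.
#' @param band_pad vertical search-band padding in pixels.
#' @return An [oct_boundary] defined exactly on `[x_first, x_last]`.
#' @export
trace_boundary <- function(cost, anchors, label = "ILM", band_pad = 40L) {
  stopifnot(inherits(cost, "cost_image"), inherits(anchors, "anchor_seq"))
  if (anchors$mode != "open")
    .lw_stop("trace_boundary needs open-mode anchors")
  .check_anchors_inside(anchors, cost)
  xs <- integer(0); zs <- integer(0); total <- 0
  for (i in seq_len(anchors$n - 1L)) {
    band <- c(min(anchors$z[i], anchors$z[i + 1L]) - band_pad,
              max(anchors$z[i], anchors$z[i + 1L]) + band_pad)
    seg <- shortest_path(cost, c(anchors$x[i], anchors$z[i]),
                         c(anchors$x[i + 1L], anchors$z[i + 1L]),
                         band = band)
    drop_first <- if (i > 1L) 2L else 1L      # joint pixel shared
    xs <- c(xs, seg$x[drop_first:seg$n])
    zs <- c(zs, seg$z[drop_first:seg$n])
    total <- total + seg$total_cost
  }
  b <- path_to_boundary(.as_pixel_path(xs, zs, total), cost$width, label)
  b$z[anchors$x + 1L] <- anchors$z              # clicks are authoritative
  b
}

#' Locally re-trace a faulty boundary stretch
#'
#' Columns spanned by `local_anchors` are replaced by a fresh live-wire
#' trace; everything outside that interval is returned untouched. No
#' smoothing is imposed at the interval ends.
#'
#' @param boundary an [oct_boundary].
#' @param cost the [cost_image] to re-trace on.
#' @param local_anchors open-mode [anchor_seq] whose x span lies inside the
#'   boundary's defined range.
#' @param band_pad vertical search-band padding in pixels.
#' @return The corrected [oct_boundary].
#' @export
correct_boundary <- function(boundary, cost, local_anchors, band_pad = 40L) {
  stopifnot(inherits(boundary, "oct_boundary"))
  a <- local_anchors$x[1L]; b <- local_anchors$x[local_anchors$n]
  def <- which(boundary$defined) - 1L
  if (!all(c(a, b) %in% def) || !all(def >= min(def) & def <= max(def)))
    if (a < min(def) || b > max(def))
      .lw_stop("correction anchors outside the boundary's defined range")
  patch <- trace_boundary(cost, local_anchors, boundary$label, band_pad)
  out <- boundary
  cols <- (a:b) + 1L
  out$z[cols] <- patch$z[cols]
  out$defined[cols] <- patch$defined[cols]
  out
}
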