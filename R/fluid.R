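# Semi-automatic fluid delineation: closed live-wire contours on an
# edge+morphology background, rasterization to binary masks, and
# small-object filtering.

#' Fluid mask with labelled components
#'
#' @param mask logical matrix (true = fluid).
#' @return An object of class `fluid_mask` with fields `mask` and
#'   `components` (data frame `object_id, area, z_min, z_max, x_min, x_max`,
#'   8-connected).
#' @export
fluid_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  lab <- .lw_label8(mask)
  n <- max(lab)
  comps <- if (n > 0) {
    do.call(rbind, lapply(seq_len(n), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      data.frame(object_id = k, area = nrow(idx),
                 z_min = min(idx[, 1L]) - 1L, z_max = max(idx[, 1L]) - 1L,
                 x_min = min(idx[, 2L]) - 1L, x_max = max(idx[, 2L]) - 1L)
    }))
  } else data.frame(object_id = integer(), area = integer(),
                    z_min = integer(), z_max = integer(),
                    x_min = integer(), x_max = integer())
  structure(list(mask = mask, components = comps, labels = lab),
            class = "fluid_mask")
}

#' @export
print.fluid_mask <- function(x, ...) {
  cat(sprintf("<fluid_mask: %d x %d px, %d component(s), %d fluid px>\n",
              nrow(x$mask), ncol(x$mask), nrow(x$components), sum(x$mask)))
  invisible(x)
}

#' Cost image for fluid contour tracing
#'
#' Canny edges, closed with a disk to bridge broken rims, then softened into
#' a graded edge map that is 1 on edge pixels and decays by 0.5 per pixel of
#' distance from the nearest edge (floored at 0); the cost is
#' `(1 - edge) + eps`, making fluid walls cheap ridges about two pixels
#' wide.
#'
#' @param image a [bscan].
#' @param canny_sigma,low,high Canny parameters (see [edge_canny]).
#' @param close_radius binary-closing disk radius in pixels (0 = identity).
#' @param eps positive cost floor.
#' @return A [cost_image].
#' @export
fluid_background <- function(image, canny_sigma = 2, low = 0.1, high = 0.3,
                             close_radius = 2, eps = 1e-6) {
  edges <- edge_canny(image, sigma = canny_sigma, low = low, high = high)
  if (close_radius > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
    edges <- as.matrix(EBImage::closing(edges * 1, kern)) > 0.5
  }
  soft <- if (any(edges)) {
    d <- as.matrix(EBImage::distmap(1 - edges))   # distance to nearest edge
    s <- 1 - 0.5 * d
    s[s < 0] <- 0
    s
  } else matrix(0, image$height, image$width)
  cost_image((1 - soft) + eps, eps = eps)
}

# cut out loops so the cycle visits no pixel twice (self-touch pruning):
# when a pixel repeats, drop everything between its two occurrences
.prune_cycle <- function(x, z) {
  keys <- paste(x, z)
  repeat {
    dup <- anyDuplicated(keys)
    if (!dup) break
    first <- match(keys[dup], keys)
    sel <- c(seq_len(first),
             if (dup < length(keys)) (dup + 1L):length(keys) else integer(0))
    x <- x[sel]; z <- z[sel]; keys <- keys[sel]
  }
  list(x = x, z = z)
}

#' Trace a closed fluid contour through rim anchors
#'
#' Concatenates minimum-cost paths between consecutive anchors and from the
#' last anchor back to the first, then prunes self-touching loops so the
#' cycle is simple.
#'
#' @param cost a [cost_image].
#' @param anchors a closed-mode [anchor_seq] (>= 3 points).
#' @return A closed `pixel_path` (first pixel not repeated at the end).
#' @export
trace_closed_contour <- function(cost, anchors) {
  stopifnot(inherits(cost, "cost_image"), inherits(anchors, "anchor_seq"))
  if (anchors$mode != "closed")
    .lw_stop("trace_closed_contour needs closed-mode anchors")
  .check_anchors_inside(anchors, cost)
  n <- anchors$n
  xs <- integer(0); zs <- integer(0); total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    seg <- shortest_path(cost, c(anchors$x[i], anchors$z[i]),
                         c(anchors$x[j], anchors$z[j]))
    sel <- seq_len(seg$n - 1L)                 # drop joint pixel
    xs <- c(xs, seg$x[sel]); zs <- c(zs, seg$z[sel])
    total <- total + seg$total_cost
  }
  pr <- .prune_cycle(xs, zs)
  if (length(pr$x) < 3L) .lw_stop("degenerate (zero-area) fluid contour")
  .as_pixel_path(pr$x, pr$z, total)
}

#' Rasterize a closed contour to a fluid mask
#'
#' Contour pixels plus every pixel enclosed by the contour (regions of the
#' complement not connected to the image border), with components labelled
#' 8-connected.
#'
#' @param contour a closed `pixel_path` (from [trace_closed_contour]).
#' @param shape `c(height, width)` of the target mask.
#' @return A [fluid_mask].
#' @export
rasterize_mask <- function(contour, shape) {
  stopifnot(inherits(contour, "pixel_path"))
  if (contour$n < 3L) .lw_stop("contour too short to enclose area")
  h <- shape[1L]; w <- shape[2L]
  ring <- matrix(FALSE, h, w)
  ring[cbind(contour$z + 1L, contour$x + 1L)] <- TRUE
  # flood the background from the border (4-connected so the 8-connected
  # ring is watertight); everything not reached is inside
  bg <- .flood_outside(ring)
  fluid_mask(!bg | ring)
}

.flood_outside <- function(ring) {
  h <- nrow(ring); w <- ncol(ring)
  outside <- matrix(FALSE, h, w)
  queue <- integer(0)
  push <- function(q, z, x) c(q, (x - 1L) * h + z)
  for (x in 1:w) queue <- push(queue, c(1L, h), c(x, x))
  for (z in 1:h) queue <- push(queue, c(z, z), c(1L, w))
  queue <- unique(queue[!ring[queue]])
  outside[queue] <- TRUE
  while (length(queue)) {
    z <- ((queue - 1L) %% h) + 1L
    x <- ((queue - 1L) %/% h) + 1L
    nxt <- integer(0)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nz <- z + d[1L]; nx <- x + d[2L]
      ok <- nz >= 1L & nz <= h & nx >= 1L & nx <= w
      idx <- (nx[ok] - 1L) * h + nz[ok]
      idx <- idx[!ring[idx] & !outside[idx]]
      if (length(idx)) {
        outside[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    queue <- unique(nxt)
  }
  outside
}

#' Drop marginally small fluid objects
#'
#' Removes connected components with area below `min_area` pixels; the
#' surviving components keep their pixels untouched.
#'
#' @param mask a [fluid_mask].
#' @param min_area minimum component area in pixels (>= 0).
#' @return The filtered [fluid_mask].
#' @export
filter_small_objects <- function(mask, min_area) {
  stopifnot(inherits(mask, "fluid_mask"))
  if (min_area < 0) .lw_stop("min_area must be >= 0")
  if (min_area == 0 || !nrow(mask$components)) return(mask)
  drop <- mask$components$object_id[mask$components$area < min_area]
  if (!length(drop)) return(mask)
  m <- mask$mask
  m[mask$labels %in% drop] <- FALSE
  fluid_mask(m)
}

#' Component table of a fluid mask
#'
#' @param mask a [fluid_mask].
#' @param bscan_id id written into each row.
#' @return Data frame `bscan_id, object_id, area_px, z_min, z_max, x_min,
#'   x_max`.
#' @export
fluid_component_table <- function(mask, bscan_id = "bscan") {
  cbind(data.frame(bscan_id = rep(bscan_id,
                                  nrow(mask$components))),
        stats::setNames(mask$components,
                        c("object_id", "area_px", "z_min", "z_max",
                          "x_min", "x_max")))
}
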