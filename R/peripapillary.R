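# Peripapillary (circumpapillary) processing: flatten the scan against a
# reference boundary, detect and remove vessel shadows, trace the eight
# peripapillary boundaries (no GCL_IPL) on the flattened image, and map the
# results back to original coordinates.

#' Coarse reference-boundary estimate
#'
#' Per-column depth of the brightest band: the argmax of a 5-px vertical
#' moving average restricted to the lower 60% of rows (the hyperreflective
#' photoreceptor/RPE complex), then median-filtered with width 15. Ties take
#' the smaller z.
#'
#' @param image a [bscan].
#' @return An [oct_boundary] (label `ONL_PR`) defined on all columns.
#' @export
estimate_reference_boundary <- function(image) {
  p <- image$pixels
  h <- image$height
  sm <- stats::filter(p, rep(1 / 5, 5), sides = 2)     # 5-px vertical MA
  sm[is.na(sm)] <- 0
  z0 <- ceiling(0.4 * h)                               # lower 60% of rows
  sub <- sm[(z0 + 1L):h, , drop = FALSE]
  idx <- apply(sub, 2L, which.max)                     # first max: smaller z
  z <- idx + z0 - 1L                                   # back to 0-based rows
  if (length(z) >= 15L) z <- runmed(z, 15L, endrule = "median")
  oct_boundary("ONL_PR", as.numeric(z))
}

#' Shift vector from a reference boundary
#'
#' Per-column downward shift obtained by subtracting each column's reference
#' depth from the maximum reference depth, rounded to whole pixels. Applying
#' it with [flatten] puts the reference boundary on one constant row.
#'
#' @param ref an [oct_boundary] defined on all columns.
#' @return Integer vector of class `shift_vector` (all >= 0, min 0).
#' @export
compute_shift_vector <- function(ref) {
  if (!all(ref$defined))
    .lw_stop("reference boundary must be defined on all columns")
  s <- as.integer(round(max(ref$z) - ref$z))
  structure(s, class = "shift_vector")
}

#' Flatten / unflatten a B-scan by per-column circular shifts
#'
#' `flatten` rotates each column downward by its shift (rows wrap from the
#' bottom to the top); `unflatten` rotates upward, so
#' `unflatten(flatten(img, s), s)` is exactly the input.
#'
#' @param image a [bscan].
#' @param s an integer shift vector of length `width`.
#' @return The shifted [bscan].
#' @export
flatten <- function(image, s) .circ_shift(image, as.integer(s))

#' @rdname flatten
#' @export
unflatten <- function(image, s) .circ_shift(image, -as.integer(s))

.circ_shift <- function(image, s) {
  if (length(s) != image$width)
    .lw_stop("shift vector length must equal the image width")
  h <- image$height
  out <- image
  rows <- 0:(h - 1L)
  for (x in seq_len(image$width)) {
    k <- s[x] %% h
    if (k != 0)
      out$pixels[, x] <- image$pixels[((rows - k) %% h) + 1L, x]
  }
  out
}

#' Detect vessel shadows on a flattened scan
#'
#' The mean intensity of each column from the IPL-INL boundary down to the
#' image bottom is taken as a lateral profile; vessel shadows are its local
#' minima (after a width-5 moving average) with prominence at least
#' `min_prominence`. The half-width is measured where the profile recovers
#' half the prominence, capped at 15 px.
#'
#' @param flat a flattened [bscan].
#' @param ipl_inl an [oct_boundary] defined on all columns.
#' @param min_prominence minimum depth of a minimum relative to its
#'   surroundings (intensity units).
#' @param min_width minimum half-width in columns for a detection.
#' @return Data frame of class `vessel_set`: `center_x` (0-based),
#'   `half_width`, `prominence`; zero rows when nothing is found.
#' @export
detect_vessels <- function(flat, ipl_inl, min_prominence = 0.05,
                           min_width = 1L) {
  if (!all(ipl_inl$defined))
    .lw_stop("IPL-INL boundary must be defined on all columns")
  h <- flat$height
  m <- vapply(seq_len(flat$width), function(x) {
    z0 <- min(h - 1L, max(0L, .round_half_up(ipl_inl$z[x])))
    mean(flat$pixels[(z0 + 1L):h, x])
  }, numeric(1))
  msm <- as.numeric(stats::filter(m, rep(1 / 5, 5), sides = 2))
  msm[is.na(msm)] <- m[is.na(msm)]
  det <- .minima_with_prominence(msm, min_prominence)
  if (nrow(det)) {
    det$half_width <- pmin(pmax(det$half_width, min_width), 15L)
    det <- det[order(det$center_x), , drop = FALSE]
  }
  structure(det, class = c("vessel_set", "data.frame"))
}

# local minima of a profile with prominence (depth relative to the lower of
# the two enclosing maxima) and half-prominence width
.minima_with_prominence <- function(m, min_prom) {
  n <- length(m)
  out <- data.frame(center_x = integer(), half_width = integer(),
                    prominence = numeric())
  if (n < 3L) return(out)
  # collapse runs of equal values so flat-bottomed minima resolve to their
  # plateau centre
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  run_is_min <- rep(FALSE, nr)
  if (nr >= 3L)
    run_is_min[2:(nr - 1L)] <- r$values[2:(nr - 1L)] < r$values[1:(nr - 2L)] &
      r$values[2:(nr - 1L)] < r$values[3:nr]
  mins <- as.integer(round((starts[run_is_min] + ends[run_is_min]) / 2))
  for (i in mins) {
    lmax <- max(m[1:i]); rmax <- max(m[i:n])
    prom <- min(lmax, rmax) - m[i]
    if (prom < min_prom) next
    thr <- m[i] + prom / 2
    l <- i; while (l > 1L && m[l] < thr) l <- l - 1L
    r <- i; while (r < n && m[r] < thr) r <- r + 1L
    hw <- max(1L, floor((r - l) / 2))
    # the dip midpoint is a far more noise-robust centre than the argmin
    out <- rbind(out, data.frame(center_x = as.integer(round((l + r) / 2)) - 1L,
                                 half_width = hw, prominence = prom))
  }
  # merge plateaus/shoulders that resolved to adjacent columns
  if (nrow(out) > 1L) {
    keep <- c(TRUE, diff(out$center_x) > out$half_width[-nrow(out)])
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Remove vessel shadows by adjacent-column substitution
#'
#' For each vessel the left half of the interval (columns
#' `center - hw .. center - 1`) is replaced by the block of columns
#' immediately left of the interval, and the right half
#' (`center .. center + hw`) by the block immediately right. Vessels
#' touching the image edge fall back to a one-sided copy with a warning;
#' all other columns are untouched.
#'
#' @param flat a flattened [bscan].
#' @param vessels a `vessel_set` from [detect_vessels].
#' @return The repaired [bscan].
#' @export
remove_vessels <- function(flat, vessels) {
  out <- flat
  w <- flat$width
  for (i in seq_len(nrow(vessels))) {
    cx <- vessels$center_x[i]; hw <- vessels$half_width[i]
    lo <- cx - hw; hi <- cx + hw
    if (lo < 0 || hi > w - 1)
      .lw_stop("vessel interval outside the image")
    left_src <- (lo - hw):(lo - 1L)
    right_src <- (hi + 1L):(hi + hw + 1L)
    left_ok <- all(left_src >= 0)
    right_ok <- all(right_src <= w - 1L)
    if (!left_ok && !right_ok) {
      .lw_warn("vessel at x=", cx, " has no intact neighbours; skipped")
      next
    }
    if (!left_ok) {
      .lw_warn("vessel at x=", cx, " touches the left edge; one-sided copy")
      src <- right_src[seq_len(hi - lo + 1L)]
      out$pixels[, (lo:hi) + 1L] <- flat$pixels[, src + 1L]
      next
    }
    if (!right_ok) {
      .lw_warn("vessel at x=", cx, " touches the right edge; one-sided copy")
      src <- rev(lo - seq_len(hi - lo + 1L))
      out$pixels[, (lo:hi) + 1L] <- flat$pixels[, src + 1L]
      next
    }
    if (hw > 0)
      out$pixels[, (lo:(cx - 1L)) + 1L] <- flat$pixels[, left_src + 1L]
    out$pixels[, (cx:hi) + 1L] <- flat$pixels[, right_src + 1L]
  }
  out
}

#' Peripapillary labels
#'
#' The eight interfaces traced in peripapillary mode (GCL_IPL is excluded).
#' @export
PERIPAPILLARY_LABELS <- setdiff(BOUNDARY_LABELS, "GCL_IPL")

#' Segment a peripapillary B-scan
#'
#' Full pipeline: estimate the reference boundary, flatten the scan with the
#' resulting shift vector, build a provisional IPL-INL curve from that
#' boundary's anchors (grid interpolation), detect and remove vessel
#' shadows, trace each requested boundary on the repaired flattened image
#' (sequential order, ROI-restricted by already-traced neighbours), and
#' unflatten the traces back to original coordinates.
#'
#' Anchors are given in *flattened* coordinates.
#'
#' @param image a [bscan] (original coordinates).
#' @param anchors named list of open-mode [anchor_seq], one per requested
#'   label; `GCL_IPL` is rejected.
#' @param config a `filter_config`.
#' @param min_prominence vessel-detection threshold (see [detect_vessels]).
#' @return A list with `boundaries` (named list of [oct_boundary] in
#'   original coordinates), `shift` (the `shift_vector`), `vessels` (the
#'   `vessel_set`) and `flat` (the repaired flattened [bscan]).
#' @export
segment_peripapillary <- function(image, anchors,
                                  config = default_filter_config(),
                                  min_prominence = 0.05) {
  labs <- names(anchors)
  if ("GCL_IPL" %in% labs)
    .lw_stop("GCL_IPL is not segmented in peripapillary mode")
  bad <- setdiff(labs, PERIPAPILLARY_LABELS)
  if (length(bad))
    .lw_stop("unknown peripapillary label(s): ", paste(bad, collapse = ", "))
  ref <- estimate_reference_boundary(image)
  s <- compute_shift_vector(ref)
  flat <- flatten(image, s)

  # provisional IPL-INL for the vessel profile: interpolate its anchors if
  # given, else fall back to the (flattened) reference boundary
  prov <- if ("IPL_INL" %in% labs)
    fit_boundary_from_points(anchors$IPL_INL, image$width, "IPL_INL",
                             height = image$height)
  else oct_boundary("IPL_INL",
                    pmin(ref$z + s, image$height - 1))
  vessels <- detect_vessels(flat, prov, min_prominence = min_prominence)
  clean <- remove_vessels(flat, vessels)

  config <- .prune_roi(config, labs)
  traced <- list()
  for (lab in segmentation_order(labs)) {
    cost <- make_background(clean, lab, config, prior = traced)
    traced[[lab]] <- trace_boundary(cost, anchors[[lab]], lab)
  }

  out <- list()
  for (lab in labs) {
    b <- traced[[lab]]
    z <- b$z - s                       # undo the downward shift
    wrapped <- b$defined & (z < 0 | z > image$height - 1)
    if (any(wrapped))
      .lw_stop("unflattened boundary ", lab, " wraps past the image on ",
               "column(s) ", paste(head(which(wrapped) - 1L, 5L),
                                   collapse = ", "))
    out[[lab]] <- oct_boundary(lab, z, defined = b$defined)
  }
  list(boundaries = out, shift = s, vessels = vessels, flat = clean)
}

#' Write a shift vector as CSV
#'
#' @param s a `shift_vector`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_shift_csv <- function(s, path) {
  write.csv(data.frame(x = seq_along(s) - 1L, shift = as.integer(s)),
            path, row.names = FALSE)
  invisible(path)
}
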