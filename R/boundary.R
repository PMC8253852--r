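#' Retinal boundary labels
#'
#' The nine interfaces the tracer knows about, ordered anatomically from the
#' vitreous down to the outer retinal pigment epithelium. Peripapillary mode
#' excludes `GCL_IPL`.
#'
#' @export
BOUNDARY_LABELS <- c("ILM", "NFL_GCL", "GCL_IPL", "IPL_INL", "INL_OPL",
                     "OPL_ONL", "ONL_PR", "PR_RPE", "RPE_OUTER")

.check_label <- function(label) {
  if (length(label) != 1L || !label %in% BOUNDARY_LABELS)
    .lw_stop("unknown boundary label '", label, "'; expected one of: ",
             paste(BOUNDARY_LABELS, collapse = ", "))
  label
}

#' Per-column boundary curve
#'
#' A boundary assigns one real-valued depth z to each image column where it
#' is defined. Sub-pixel z values are allowed (averaging and interpolation
#' produce them); rasterization rounds half-up.
#'
#' @param label one of [BOUNDARY_LABELS].
#' @param z numeric vector of depths, length = image width; `NA` where
#'   undefined.
#' @param defined optional logical mask; defaults to `!is.na(z)`.
#' @param height optional image height used to validate the z range.
#' @return An object of class `oct_boundary` with fields `label`, `z`,
#'   `defined`.
#' @export
oct_boundary <- function(label, z, defined = NULL, height = NULL) {
  .check_label(label)
  z <- as.numeric(z)
  if (is.null(defined)) defined <- !is.na(z)
  defined <- as.logical(defined)
  if (length(defined) != length(z))
    .lw_stop("'defined' must match the length of 'z'")
  z[!defined] <- NA_real_
  if (any(defined & !is.finite(z)))
    .lw_stop("defined z values must be finite")
  if (!is.null(height) && any(defined & (z < 0 | z > height - 1)))
    .lw_stop("boundary z outside [0, height-1]")
  structure(list(label = label, z = z, defined = defined),
            class = "oct_boundary")
}

#' @export
print.oct_boundary <- function(x, ...) {
  rng <- range(which(x$defined))
  cat(sprintf("<oct_boundary %s: width %d, defined on x [%d, %d]>\n",
              x$label, length(x$z), rng[1] - 1L, rng[2] - 1L))
  invisible(x)
}

#' Anchor (click) sequences
#'
#' Ordered integer (x, z) seed points standing in for user clicks. Open mode
#' (layer tracing) requires strictly increasing x and at least 2 points;
#' closed mode (fluid contours) requires at least 3.
#'
#' @param x,z integer coordinate vectors (0-based).
#' @param mode `"open"` or `"closed"`.
#' @return An object of class `anchor_seq`.
#' @export
anchor_seq <- function(x, z, mode = c("open", "closed")) {
  mode <- match.arg(mode)
  x <- as.integer(round(x)); z <- as.integer(round(z))
  if (length(x) != length(z)) .lw_stop("x and z must have equal length")
  if (anyNA(x) || anyNA(z)) .lw_stop("anchors must be finite")
  need <- if (mode == "open") 2L else 3L
  if (length(x) < need)
    .lw_stop(mode, "-mode anchors need at least ", need, " points")
  if (mode == "open" && any(diff(x) <= 0))
    .lw_stop("open-mode anchors must have strictly increasing x")
  structure(list(x = x, z = z, mode = mode, n = length(x)),
            class = "anchor_seq")
}

.check_anchors_inside <- function(anchors, image) {
  if (any(anchors$x < 0 | anchors$x > image$width - 1 |
          anchors$z < 0 | anchors$z > image$height - 1))
    .lw_stop("anchor points fall outside the image")
  invisible(anchors)
}

#' Write/read boundary tables as CSV
#'
#' Long format with columns `bscan_id, label, x, z, defined`. The roundtrip
#' is lossless for finite z at 6 decimals.
#'
#' @param boundaries list of [oct_boundary] (all the same width).
#' @param path CSV file path.
#' @param bscan_id id written into each row.
#' @return `write_boundaries_csv` returns `path` invisibly;
#'   `read_boundaries_csv` returns a named list of lists of `oct_boundary`,
#'   one element per `bscan_id` in the file.
#' @export
write_boundaries_csv <- function(boundaries, path, bscan_id = "bscan") {
  ws <- vapply(boundaries, function(b) length(b$z), integer(1))
  if (length(ws) && length(unique(ws)) != 1L)
    .lw_stop("boundaries must share width")
  ids <- if (length(bscan_id) == length(boundaries)) bscan_id
         else rep(bscan_id[1L], length(boundaries))
  rows <- lapply(seq_along(boundaries), function(i) {
    b <- boundaries[[i]]
    data.frame(bscan_id = ids[i], label = b$label,
               x = seq_along(b$z) - 1L,
               z = ifelse(b$defined, sprintf("%.6f", b$z), ""),
               defined = b$defined, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(bscan_id = character(), label = character(),
                         x = integer(), z = character(), defined = logical())
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boundaries_csv
#' @export
read_boundaries_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(bscan_id = "character", label = "character"))
  if (!nrow(df)) return(list())
  bad <- setdiff(unique(df$label), BOUNDARY_LABELS)
  if (length(bad))
    .lw_stop("unknown boundary label(s) in ", path, ": ",
             paste(bad, collapse = ", "))
  out <- list()
  for (id in unique(df$bscan_id)) {
    sub <- df[df$bscan_id == id, , drop = FALSE]
    bl <- list()
    for (lab in unique(sub$label)) {
      s <- sub[sub$label == lab, , drop = FALSE]
      s <- s[order(s$x), , drop = FALSE]
      width <- max(s$x) + 1L
      z <- rep(NA_real_, width)
      zi <- suppressWarnings(as.numeric(s$z))
      z[s$x + 1L] <- ifelse(s$defined, zi, NA_real_)
      bl[[lab]] <- oct_boundary(lab, z)
    }
    out[[id]] <- bl
  }
  out
}

#' Write/read anchor (click) tables as CSV
#'
#' Columns `bscan_id, label, group, order, x, z, mode`; `group` separates
#' multiple fluid contours on one B-scan (0 for open-mode layer anchors).
#'
#' @param anchors named list: `anchors[[bscan_id]][[label]]` is an
#'   [anchor_seq] or a list of them (closed mode, one per group).
#' @param path CSV file path.
#' @return `write_anchors_csv` returns `path` invisibly; `read_anchors_csv`
#'   returns the nested list structure described above.
#' @export
write_anchors_csv <- function(anchors, path) {
  rows <- list()
  for (id in names(anchors)) {
    for (lab in names(anchors[[id]])) {
      a <- anchors[[id]][[lab]]
      groups <- if (inherits(a, "anchor_seq")) list(a) else a
      for (g in seq_along(groups)) {
        aa <- groups[[g]]
        rows[[length(rows) + 1L]] <- data.frame(
          bscan_id = id, label = lab, group = g - 1L,
          order = seq_len(aa$n) - 1L, x = aa$x, z = aa$z, mode = aa$mode,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(bscan_id = character(), label = character(),
                         group = integer(), order = integer(),
                         x = integer(), z = integer(), mode = character())
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_anchors_csv
#' @export
read_anchors_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(bscan_id = "character", label = "character"))
  out <- list()
  if (!nrow(df)) return(out)
  for (id in unique(df$bscan_id)) {
    sub <- df[df$bscan_id == id, , drop = FALSE]
    out[[id]] <- list()
    for (lab in unique(sub$label)) {
      s <- sub[sub$label == lab, , drop = FALSE]
      groups <- lapply(sort(unique(s$group)), function(g) {
        sg <- s[s$group == g, , drop = FALSE]
        sg <- sg[order(sg$order), , drop = FALSE]
        anchor_seq(sg$x, sg$z, mode = sg$mode[1L])
      })
      out[[id]][[lab]] <- if (length(groups) == 1L &&
                              groups[[1L]]$mode == "open") groups[[1L]]
                          else groups
    }
  }
  out
}
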