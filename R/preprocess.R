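# Boundary-specific preprocessing: each retinal interface gets its own
# "background" (cost) image in which exactly that interface is a cheap ridge.
# The chain is denoise -> polarity-aware vertical gradient -> morphological
# cleaning -> gamma contrast -> ROI masking by already-found neighbours.

# reflectivity steps down the retina fix each interface's gradient polarity
.DEFAULT_POLARITY <- c(
  ILM = "dark_to_light", NFL_GCL = "light_to_dark", GCL_IPL = "dark_to_light",
  IPL_INL = "light_to_dark", INL_OPL = "dark_to_light",
  OPL_ONL = "light_to_dark", ONL_PR = "dark_to_light",
  PR_RPE = "dark_to_light", RPE_OUTER = "light_to_dark")

# strongest interfaces first; each later one is ROI-restricted by neighbours
# (ONL_PR before PR_RPE: the ONL-photoreceptor step is the strongest
# same-polarity edge in the outer retina and must be excluded from the much
# weaker PR_RPE search region)
.SEGMENTATION_ORDER <- c("ILM", "RPE_OUTER", "ONL_PR", "PR_RPE", "IPL_INL",
                         "OPL_ONL", "INL_OPL", "NFL_GCL", "GCL_IPL")

.DEFAULT_ROI <- list(
  ILM       = list(),
  RPE_OUTER = list(roi_above = list(label = "ILM", offset = 2)),
  ONL_PR    = list(roi_above = list(label = "ILM", offset = 2),
                   roi_below = list(label = "RPE_OUTER", offset = 2)),
  PR_RPE    = list(roi_above = list(label = "ONL_PR", offset = 6),
                   roi_below = list(label = "RPE_OUTER", offset = 2)),
  IPL_INL   = list(roi_above = list(label = "ILM", offset = 2),
                   roi_below = list(label = "ONL_PR", offset = 2)),
  OPL_ONL   = list(roi_above = list(label = "IPL_INL", offset = 2),
                   roi_below = list(label = "ONL_PR", offset = 2)),
  INL_OPL   = list(roi_above = list(label = "IPL_INL", offset = 2),
                   roi_below = list(label = "OPL_ONL", offset = 2)),
  NFL_GCL   = list(roi_above = list(label = "ILM", offset = 2),
                   roi_below = list(label = "IPL_INL", offset = 2)),
  GCL_IPL   = list(roi_above = list(label = "NFL_GCL", offset = 2),
                   roi_below = list(label = "IPL_INL", offset = 2)))

.FILTER_KEYS <- c("gaussian_sigma", "polarity", "morph_radius", "roi_above",
                  "roi_below", "contrast_gamma")

#' Per-boundary filter configuration
#'
#' One record per boundary label controlling the cost-image pipeline:
#' `gaussian_sigma` (denoising, px), `polarity` (`"dark_to_light"` keeps
#' downward intensity increases, `"light_to_dark"` the decreases),
#' `morph_radius` (horizontal cleaning element half-length, px),
#' `contrast_gamma` (edge map exponent), and optional `roi_above` /
#' `roi_below` constraints `list(label =, offset =)` restricting the search
#' region relative to previously traced neighbours. All values are
#' overridable; [read_filter_config] loads the same structure from JSON.
#'
#' @param gaussian_sigma,morph_radius,contrast_gamma default numeric values
#'   applied to every record.
#' @return A named list (class `filter_config`) with one record per label in
#'   [BOUNDARY_LABELS].
#' @export
default_filter_config <- function(gaussian_sigma = 1.5, morph_radius = 2,
                                  contrast_gamma = 1.0) {
  cfg <- lapply(BOUNDARY_LABELS, function(lab) {
    rec <- list(gaussian_sigma = gaussian_sigma,
                polarity = unname(.DEFAULT_POLARITY[[lab]]),
                morph_radius = morph_radius,
                roi_above = .DEFAULT_ROI[[lab]]$roi_above,
                roi_below = .DEFAULT_ROI[[lab]]$roi_below,
                contrast_gamma = contrast_gamma)
    rec
  })
  names(cfg) <- BOUNDARY_LABELS
  structure(cfg, class = "filter_config")
}

.check_filter_record <- function(rec, lab) {
  unknown <- setdiff(names(rec), .FILTER_KEYS)
  if (length(unknown))
    .lw_stop("unknown filter-config key(s) for ", lab, ": ",
             paste(unknown, collapse = ", "))
  if (is.null(rec$gaussian_sigma) || rec$gaussian_sigma < 0)
    .lw_stop(lab, ": gaussian_sigma must be >= 0")
  if (is.null(rec$morph_radius) || rec$morph_radius < 0)
    .lw_stop(lab, ": morph_radius must be >= 0")
  if (!rec$polarity %in% c("dark_to_light", "light_to_dark"))
    .lw_stop(lab, ": polarity must be dark_to_light or light_to_dark")
  for (side in c("roi_above", "roi_below")) {
    r <- rec[[side]]
    if (!is.null(r)) {
      .check_label(r$label)
      if (is.null(r$offset) || r$offset < 0)
        .lw_stop(lab, ": ", side, " offset must be >= 0")
    }
  }
  rec
}

#' Read/write filter configuration JSON
#'
#' The JSON file holds one object per boundary label with the keys described
#' in [default_filter_config]; unknown keys or labels are rejected. Partial
#' files are completed with defaults.
#'
#' @param path JSON file path.
#' @param config a `filter_config`.
#' @return `read_filter_config` returns a validated `filter_config`;
#'   `write_filter_config` returns `path` invisibly.
#' @export
read_filter_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bad <- setdiff(names(raw), BOUNDARY_LABELS)
  if (length(bad))
    .lw_stop("unknown boundary label(s) in config: ",
             paste(bad, collapse = ", "))
  cfg <- default_filter_config()
  for (lab in names(raw)) {
    rec <- utils::modifyList(cfg[[lab]], raw[[lab]])
    rec <- .check_filter_record(rec, lab)
    # keep the full key set (NULL for absent ROI sides) so configs compare
    # structurally regardless of the JSON trip
    cfg[[lab]] <- stats::setNames(lapply(.FILTER_KEYS, function(k) rec[[k]]),
                                  .FILTER_KEYS)
  }
  cfg
}

#' @rdname read_filter_config
#' @export
write_filter_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Gaussian denoising
#'
#' @param image a [bscan].
#' @param sigma Gaussian standard deviation in pixels; 0 is the identity.
#' @return The smoothed [bscan].
#' @export
denoise <- function(image, sigma) {
  if (sigma < 0) .lw_stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  out <- image
  out$pixels <- .as_unit_interval(as.matrix(EBImage::gblur(image$pixels,
                                                           sigma = sigma)))
  out
}

#' Polarity-rectified vertical gradient
#'
#' Central-difference derivative along depth (one-sided at the first and
#' last row). `dark_to_light` keeps the positive part (intensity increasing
#' downward), `light_to_dark` the negated negative part. The map is rescaled
#' to \[0, 1\] by its maximum; an all-zero map stays zero.
#'
#' @param image a [bscan].
#' @param polarity `"dark_to_light"` or `"light_to_dark"`.
#' @return A numeric matrix in \[0, 1\] (an edge map).
#' @export
signed_vertical_gradient <- function(image,
                                     polarity = c("dark_to_light",
                                                  "light_to_dark")) {
  polarity <- match.arg(polarity)
  p <- image$pixels
  h <- nrow(p)
  g <- matrix(0, h, ncol(p))
  if (h >= 3L)
    g[2:(h - 1L), ] <- (p[3:h, ] - p[1:(h - 2L), ]) / 2
  g[1L, ] <- p[2L, ] - p[1L, ]
  g[h, ] <- p[h, ] - p[h - 1L, ]
  e <- if (polarity == "dark_to_light") pmax(g, 0) else pmax(-g, 0)
  mx <- max(e)
  if (mx > 0) e <- e / mx
  e
}

#' Morphological edge-map cleaning
#'
#' Grayscale closing then opening with a horizontal line structuring element
#' of half-length `radius`: closing bridges small gaps along a boundary
#' ridge, the opening then removes isolated speckle responses.
#'
#' @param edge numeric edge map in \[0, 1\].
#' @param radius element half-length in pixels; 0 is the identity.
#' @return The cleaned edge map.
#' @export
morph_clean <- function(edge, radius) {
  if (radius < 0) .lw_stop("radius must be >= 0")
  if (radius == 0) return(edge)
  kern <- matrix(1, nrow = 1L, ncol = 2L * as.integer(radius) + 1L)
  out <- as.matrix(EBImage::opening(EBImage::closing(edge, kern), kern))
  .as_unit_interval(out)
}

#' Region-of-interest mask from neighbouring boundaries
#'
#' True strictly inside the band running from `roi_above`'s boundary plus
#' its offset down to `roi_below`'s boundary minus its offset; an absent
#' constraint leaves that side open. Columns where the two constraints cross
#' come back all-false with a warning.
#'
#' @param shape `c(height, width)` of the target image.
#' @param prior named list of already-traced [oct_boundary] objects.
#' @param roi_above,roi_below `list(label =, offset =)` or `NULL`.
#' @return A logical matrix of the given shape.
#' @export
roi_mask <- function(shape, prior = list(), roi_above = NULL,
                     roi_below = NULL) {
  h <- shape[1L]; w <- shape[2L]
  get_prior <- function(r) {
    b <- prior[[r$label]]
    if (is.null(b))
      .lw_stop("ROI constraint needs boundary '", r$label,
               "' which has not been traced")
    b
  }
  lo <- rep(0, w); hi <- rep(h - 1, w)
  if (!is.null(roi_above)) {
    b <- get_prior(roi_above)
    lo <- ifelse(b$defined, b$z + roi_above$offset, lo)
  }
  if (!is.null(roi_below)) {
    b <- get_prior(roi_below)
    hi <- ifelse(b$defined, b$z - roi_below$offset, hi)
  }
  crossed <- lo > hi
  if (any(crossed))
    .lw_warn("ROI constraints cross on ", sum(crossed),
             " column(s); those columns are masked out")
  rows <- matrix(0:(h - 1), h, w)
  mask <- sweep(rows, 2L, lo, ">=") & sweep(rows, 2L, hi, "<=")
  mask[, crossed] <- FALSE
  mask
}

#' Build the boundary-specific cost image
#'
#' Full preprocessing chain for one interface: [denoise] ->
#' [signed_vertical_gradient] -> [morph_clean] -> gamma contrast
#' (`edge^gamma`) -> ROI masking (edge zeroed outside) -> cost
#' `(1 - edge) + eps`. The resulting cost is strictly positive and cheapest
#' exactly on the targeted interface.
#'
#' @param image a [bscan].
#' @param label the boundary to sharpen.
#' @param config a `filter_config` (defaults to [default_filter_config]).
#' @param prior named list of already-traced [oct_boundary] objects used by
#'   the record's ROI constraints.
#' @param eps positive cost floor.
#' @return A [cost_image].
#' @export
make_background <- function(image, label, config = default_filter_config(),
                            prior = list(), eps = 1e-6) {
  .check_label(label)
  rec <- config[[label]]
  if (is.null(rec)) .lw_stop("config has no record for ", label)
  den <- denoise(image, rec$gaussian_sigma)
  edge <- signed_vertical_gradient(den, rec$polarity)
  edge <- morph_clean(edge, rec$morph_radius)
  if (rec$contrast_gamma != 1) edge <- edge^rec$contrast_gamma
  if (!is.null(rec$roi_above) || !is.null(rec$roi_below)) {
    m <- roi_mask(c(image$height, image$width), prior,
                  rec$roi_above, rec$roi_below)
    edge[!m] <- 0
  }
  cost_image((1 - edge) + eps, eps = eps)
}

# keep only ROI references to boundaries present in `prior` (the sequential
# driver traces a subset of labels; constraints to untraced ones are dropped)
.prune_roi <- function(config, labels_available) {
  for (lab in names(config)) {
    for (side in c("roi_above", "roi_below")) {
      r <- config[[lab]][[side]]
      if (!is.null(r) && !r$label %in% labels_available)
        config[[lab]][side] <- list(NULL)
    }
  }
  config
}

#' Sequential tracing order
#'
#' The order in which the macular driver traces boundaries: strongest
#' interfaces first, so later, weaker ones can be ROI-restricted by their
#' already-found neighbours.
#'
#' @param labels labels to order (default: all nine).
#' @return The labels sorted into tracing order.
#' @export
segmentation_order <- function(labels = BOUNDARY_LABELS) {
  .SEGMENTATION_ORDER[.SEGMENTATION_ORDER %in% labels]
}
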