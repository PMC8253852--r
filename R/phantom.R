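# Synthetic B-scan phantoms with exact ground truth: horizontally layered
# reflectivity bands with smooth curvilinear boundaries, an optional foveal
# depression, optional peripapillary-style sinusoidal curvature, dark
# vertical vessel shadows, dark elliptical fluid blobs, and multiplicative
# speckle noise. Ground-truth boundaries, the fluid mask and simulated
# clicks come back alongside the image, forming self-contained test cases.

# qualitative OCT reflectivity ordering, vitreous (top) to choroid (bottom)
.PHANTOM_BANDS <- c(vitreous = 0.05, NFL = 0.55, GCL = 0.35, IPL = 0.45,
                    INL = 0.25, OPL = 0.45, ONL = 0.15, PR = 0.75,
                    RPE = 0.85, choroid = 0.30)

# nominal layer thicknesses (px) below the ILM, at ~3.9 um axial pitch
.PHANTOM_THICKNESS <- c(NFL = 20, GCL = 25, IPL = 25, INL = 20, OPL = 18,
                        ONL = 50, PR = 18, RPE = 15)

# how strongly the foveal pit depresses each boundary (inner ones most)
.FOVEA_WEIGHT <- c(ILM = 1, NFL_GCL = 0.8, GCL_IPL = 0.65, IPL_INL = 0.5,
                   INL_OPL = 0.3, OPL_ONL = 0.12, ONL_PR = 0, PR_RPE = 0,
                   RPE_OUTER = 0)

# run expr with a local, restored RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Parameters of the synthetic B-scan generator. Defaults emulate a
#' fovea-centred macular scan at Spectralis-like geometry (496 x 512 px).
#'
#' @param height,width image size in pixels.
#' @param band_intensities 10 per-layer mean reflectivities in \[0, 1\],
#'   vitreous to choroid.
#' @param ilm_depth mean ILM depth in pixels.
#' @param thickness named layer thicknesses in pixels (see defaults).
#' @param fovea `list(center_x =, depth =, width =)` foveal pit (px), or
#'   `NULL` for none.
#' @param curvature `list(amplitude =, period =, phase =)` sinusoidal
#'   vertical displacement of all boundaries (peripapillary-style), or
#'   `NULL`.
#' @param speckle_sigma multiplicative Gaussian noise scale.
#' @param vessels data frame / list of `center_x`, `width`, `darkening`
#'   records for vertical shadow stripes below the ILM.
#' @param fluids data frame / list of `center_x, center_z, ax, az,
#'   intensity` records for dark elliptical blobs.
#' @param seed integer seed; generation is fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 496L, width = 512L,
                         band_intensities = .PHANTOM_BANDS,
                         ilm_depth = 150,
                         thickness = .PHANTOM_THICKNESS,
                         fovea = list(center_x = width / 2, depth = 60,
                                      width = 40),
                         curvature = NULL,
                         speckle_sigma = 0.05,
                         vessels = NULL,
                         fluids = NULL,
                         seed = 1L) {
  stopifnot(length(band_intensities) == 10L, length(thickness) == 8L,
            speckle_sigma >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 band_intensities = band_intensities,
                 ilm_depth = ilm_depth, thickness = thickness,
                 fovea = fovea, curvature = curvature,
                 speckle_sigma = speckle_sigma,
                 vessels = vessels, fluids = fluids,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# ground-truth boundary depths, one row per label, columns = x
.phantom_boundaries <- function(spec) {
  x <- 0:(spec$width - 1L)
  base <- spec$ilm_depth + c(0, cumsum(spec$thickness))
  zb <- matrix(base, nrow = 9L, ncol = spec$width)
  rownames(zb) <- BOUNDARY_LABELS
  if (!is.null(spec$curvature)) {
    cv <- spec$curvature
    phase <- cv$phase %||% 0
    bow <- cv$amplitude * sin(2 * pi * x / cv$period + phase)
    zb <- sweep(zb, 2L, bow, `+`)
  }
  if (!is.null(spec$fovea)) {
    fv <- spec$fovea
    dip <- fv$depth * exp(-(x - fv$center_x)^2 / (2 * fv$width^2))
    zb <- zb + outer(.FOVEA_WEIGHT[BOUNDARY_LABELS], dip)
  }
  if (any(apply(zb, 2L, diff) < 2))
    .lw_stop("phantom boundaries closer than 2 px; adjust the spec")
  if (min(zb) < 1 || max(zb) > spec$height - 2)
    .lw_stop("phantom boundaries leave the image; adjust the spec")
  zb
}

#' Generate a synthetic B-scan with ground truth
#'
#' Renders the reflectivity bands between the ground-truth boundaries with
#' sub-pixel (linear partial-volume) edges, stamps fluids and vessel
#' shadows, applies multiplicative speckle `I * (1 + N(0, sigma))` and clips
#' to \[0, 1\].
#'
#' @param spec a [phantom_spec].
#' @return A list with `image` ([bscan]), `boundaries` (named list of nine
#'   ground-truth [oct_boundary]), `fluid` ([fluid_mask]) and `spec`.
#' @export
generate_bscan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  zb <- .phantom_boundaries(spec)
  h <- spec$height; w <- spec$width
  bands <- as.numeric(spec$band_intensities)
  rows <- 0:(h - 1L)
  img <- matrix(0, h, w)
  for (x in seq_len(w)) {
    zx <- zb[, x]
    v <- bands[findInterval(rows, zx) + 1L]
    # partial-volume blend in the pixel containing each boundary
    r0 <- .round_half_up(zx)                  # pixel covering [r0-.5, r0+.5)
    frac_above <- zx - (r0 - 0.5)
    for (k in 1:9)
      v[r0[k] + 1L] <- bands[k] * frac_above[k] +
        bands[k + 1L] * (1 - frac_above[k])
    img[, x] <- v
  }

  fluid <- matrix(FALSE, h, w)
  if (!is.null(spec$fluids)) {
    fl <- as.data.frame(spec$fluids)
    zz <- matrix(rows, h, w)
    xx <- matrix(0:(w - 1L), h, w, byrow = TRUE)
    for (i in seq_len(nrow(fl))) {
      inside <- ((xx - fl$center_x[i]) / fl$ax[i])^2 +
                ((zz - fl$center_z[i]) / fl$az[i])^2 <= 1
      img[inside] <- fl$intensity[i]
      fluid <- fluid | inside
    }
  }

  if (!is.null(spec$vessels)) {
    vs <- as.data.frame(spec$vessels)
    for (i in seq_len(nrow(vs))) {
      lo <- max(0L, .round_half_up(vs$center_x[i] - vs$width[i] / 2))
      hi <- min(w - 1L, .round_half_up(vs$center_x[i] + vs$width[i] / 2))
      for (x in lo:hi) {
        top <- .round_half_up(zb["ILM", x + 1L])
        sel <- (top + 1L):h
        img[sel, x + 1L] <- img[sel, x + 1L] * (1 - vs$darkening[i])
      }
    }
  }

  if (spec$speckle_sigma > 0)
    img <- .with_seed(spec$seed,
                      img * (1 + matrix(rnorm(h * w, 0, spec$speckle_sigma),
                                        h, w)))
  img <- .as_unit_interval(img)

  gt <- lapply(BOUNDARY_LABELS, function(lab)
    oct_boundary(lab, zb[lab, ]))
  names(gt) <- BOUNDARY_LABELS
  list(image = bscan(img, scale_x = 0.0117, scale_z = 0.0039,
                     id = sprintf("phantom_%06d", spec$seed)),
       boundaries = gt, fluid = fluid_mask(fluid), spec = spec)
}

#' Simulate user clicks on a ground-truth boundary
#'
#' Anchors are placed at [grid_lines]-style columns (first and last forced
#' to the image edges) on the ground-truth depth, with vertical Gaussian
#' jitter (rounded and clipped) emulating imprecise clicking.
#'
#' @param gt a ground-truth [oct_boundary] defined on all columns.
#' @param n_anchors number of clicks (>= 2).
#' @param jitter_sigma vertical jitter standard deviation in pixels.
#' @param seed integer seed.
#' @param height image height used for clipping.
#' @return An open-mode [anchor_seq].
#' @export
simulate_clicks <- function(gt, n_anchors, jitter_sigma = 1, seed = 1L,
                            height = 496L) {
  if (n_anchors < 2L) .lw_stop("need at least 2 clicks")
  w <- length(gt$z)
  x <- grid_lines(w, n_anchors)
  x[1L] <- 0L
  x[n_anchors] <- w - 1L
  z <- gt$z[x + 1L]
  if (jitter_sigma > 0)
    z <- z + .with_seed(seed, rnorm(n_anchors, 0, jitter_sigma))
  z <- pmin(pmax(.round_half_up(z), 0), height - 1L)
  anchor_seq(x, z, mode = "open")
}

#' Simulate rim clicks on a fluid component
#'
#' Places `n_anchors` points on the component's outer contour at equal
#' arc-length spacing, ordered counter-clockwise; the starting point is
#' chosen by the seed.
#'
#' @param mask a [fluid_mask].
#' @param object_id which component to click on.
#' @param n_anchors number of rim clicks (>= 3).
#' @param seed integer seed.
#' @return A closed-mode [anchor_seq].
#' @export
simulate_fluid_clicks <- function(mask, object_id = 1L, n_anchors = 5L,
                                  seed = 1L) {
  stopifnot(inherits(mask, "fluid_mask"))
  comp <- mask$labels == object_id
  if (!any(comp)) .lw_stop("no component with object_id ", object_id)
  # contour = component pixels with a 4-neighbour outside the component
  h <- nrow(comp); w <- ncol(comp)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- comp
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
              pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  contour <- which(comp & !interior, arr.ind = TRUE)
  if (nrow(contour) < n_anchors)
    .lw_stop("component contour has fewer pixels than requested anchors")
  cz <- contour[, 1L] - 1L; cx <- contour[, 2L] - 1L
  # counter-clockwise order around the centroid (z grows downward)
  ang <- atan2(-(cz - mean(cz)), cx - mean(cx))
  ord <- order(ang)
  cz <- cz[ord]; cx <- cx[ord]
  arc <- cumsum(c(0, sqrt(diff(cx)^2 + diff(cz)^2)))
  total <- arc[length(arc)] +
    sqrt((cx[1L] - cx[length(cx)])^2 + (cz[1L] - cz[length(cz)])^2)
  start <- .with_seed(seed, runif(1, 0, total))
  targets <- (start + total * (0:(n_anchors - 1L)) / n_anchors) %% total
  idx <- vapply(targets, function(t) which.min(abs(arc - t)), integer(1))
  anchor_seq(cx[idx], cz[idx], mode = "closed")
}
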