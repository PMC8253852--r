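# PNG/TIFF B-scan input and overlay/mask output.

# fixed drawing palette, one colour per boundary label (RGB in [0,1])
.BOUNDARY_PALETTE <- list(
  ILM       = c(1.00, 0.10, 0.10),
  NFL_GCL   = c(1.00, 0.60, 0.00),
  GCL_IPL   = c(0.95, 0.90, 0.10),
  IPL_INL   = c(0.10, 0.85, 0.10),
  INL_OPL   = c(0.10, 0.85, 0.85),
  OPL_ONL   = c(0.15, 0.35, 1.00),
  ONL_PR    = c(0.65, 0.25, 1.00),
  PR_RPE    = c(1.00, 0.20, 0.80),
  RPE_OUTER = c(0.55, 0.35, 0.10))

.FLUID_COLOR <- c(0.1, 0.5, 1.0)   # translucent fill for fluid masks

# round half up (rasterization convention)
.round_half_up <- function(z) floor(z + 0.5)

.read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .lw_stop("unsupported image format '", ext, "' for ", path,
             " (PNG/TIFF supported)"))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    img <- if (nc >= 3L)
      0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    else img[, , 1L]
  }
  img
}

#' Read a stack of B-scan images as a volume
#'
#' Each image is converted to grayscale (luminosity weights for RGB) and
#' min-max rescaled to \[0, 1\] per image; a constant image maps to all
#' zeros.
#'
#' @param paths character vector of PNG/TIFF file paths, all the same size.
#' @param scale_x,scale_z optional physical scales (mm/pixel).
#' @return An [oct_volume] with `source_format = "images"`.
#' @export
read_image_stack <- function(paths, scale_x = NA_real_, scale_z = NA_real_) {
  if (!length(paths)) .lw_stop("no image paths given")
  mats <- lapply(paths, .read_gray)
  dims <- vapply(mats, dim, integer(2))
  bad <- which(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L])
  if (length(bad))
    .lw_stop("image dimensions differ from the first image: ",
             paste(basename(paths[bad]), collapse = ", "))
  bscans <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    rng <- range(m)
    m <- if (rng[2L] > rng[1L]) (m - rng[1L]) / (rng[2L] - rng[1L])
         else matrix(0, nrow(m), ncol(m))   # zero-range rule
    bscan(m, scale_x = scale_x, scale_z = scale_z,
          id = tools::file_path_sans_ext(basename(paths[i])))
  })
  oct_volume(bscans, source_format = "images")
}

#' Write a segmentation overlay image
#'
#' Renders the B-scan as 8-bit RGB with each boundary drawn in its fixed
#' palette colour (rasterized by rounding z half-up) and, optionally, a
#' fluid mask blended translucently.
#'
#' @param image a [bscan].
#' @param boundaries list of [oct_boundary] objects (may be empty).
#' @param mask optional [fluid_mask] with the same geometry.
#' @param path output PNG path.
#' @param mask_alpha blend weight of the mask colour.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, boundaries = list(), mask = NULL, path,
                          mask_alpha = 0.4) {
  px <- image$pixels
  rgb <- array(px, dim = c(image$height, image$width, 3L))
  if (!is.null(mask)) {
    if (!all(dim(mask$mask) == dim(px)))
      .lw_stop("mask geometry does not match the image")
    sel <- mask$mask
    for (ch in 1:3)
      rgb[, , ch][sel] <- (1 - mask_alpha) * rgb[, , ch][sel] +
        mask_alpha * .FLUID_COLOR[ch]
  }
  for (b in boundaries) {
    if (length(b$z) != image$width)
      .lw_stop("boundary width does not match the image")
    col <- .BOUNDARY_PALETTE[[b$label]]
    xs <- which(b$defined)
    zs <- .round_half_up(b$z[xs])
    ok <- zs >= 0 & zs <= image$height - 1
    idx <- cbind(zs[ok] + 1L, xs[ok])
    for (ch in 1:3) {
      m <- rgb[, , ch]; m[idx] <- col[ch]; rgb[, , ch] <- m
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write/read a binary mask as a 0/255 PNG
#'
#' @param mask logical matrix or [fluid_mask].
#' @param path PNG file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "fluid_mask")) mask$mask else mask
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}
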