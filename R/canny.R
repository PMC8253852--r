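# Canny edge detection: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantized gradient direction, and hysteresis
# thresholding (weak edges kept only in 8-connected components that contain
# a strong pixel). Thresholds apply to the gradient magnitude rescaled to
# [0, 1] by its maximum.

.sobel <- function(p) {
  h <- nrow(p); w <- ncol(p)
  # replicate borders
  pad <- rbind(p[1L, , drop = FALSE], p, p[h, , drop = FALSE])
  pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, w, drop = FALSE])
  sh <- function(dz, dx) pad[(2L + dz):(h + 1L + dz),
                             (2L + dx):(w + 1L + dx), drop = FALSE]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gz <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  list(gx = gx, gz = gz)
}

#' Canny edge detection
#'
#' @param image a [bscan] (or plain numeric matrix in \[0, 1\]).
#' @param sigma Gaussian smoothing scale in pixels.
#' @param low,high hysteresis thresholds on the max-normalized gradient
#'   magnitude; `0 <= low < high <= 1`.
#' @return A logical edge mask.
#' @export
edge_canny <- function(image, sigma = 2, low = 0.1, high = 0.3) {
  if (!(low >= 0 && low < high && high <= 1))
    .lw_stop("need 0 <= low < high <= 1")
  p <- if (inherits(image, "bscan")) image$pixels else image
  if (sigma > 0) p <- as.matrix(EBImage::gblur(p, sigma = sigma))
  g <- .sobel(p)
  mag <- sqrt(g$gx^2 + g$gz^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(p), ncol(p)))
  mag <- mag / mx
  h <- nrow(p); w <- ncol(p)
  # quantize direction to 0/45/90/135 degrees and suppress non-maxima
  ang <- atan2(g$gz, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))  # (dz, dx)
  padm <- matrix(0, h + 2L, w + 2L)
  padm[2:(h + 1L), 2:(w + 1L)] <- mag
  zi <- matrix(2:(h + 1L), h, w)
  xi <- matrix(2:(w + 1L), h, w, byrow = TRUE)
  keep <- matrix(FALSE, h, w)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    sel <- sector == s
    n1 <- padm[cbind(zi[sel] + d[1L], xi[sel] + d[2L])]
    n2 <- padm[cbind(zi[sel] - d[1L], xi[sel] - d[2L])]
    keep[sel] <- mag[sel] >= n1 & mag[sel] >= n2
  }
  thin <- mag * keep
  weak <- thin >= low
  strong <- thin >= high
  if (!any(strong)) return(matrix(FALSE, h, w))
  lab <- .lw_label8(weak)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, h, w)
}
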