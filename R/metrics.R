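# Agreement and quality metrics: unsigned boundary error, gold-standard
# averaging, irregularity index, Dice overlap, Bland-Altman limits of
# agreement, repeatability reports.

.common_cols <- function(b1, b2) which(b1$defined & b2$defined)

#' Unsigned boundary error
#'
#' Mean per-column absolute depth difference between two boundary curves,
#' `sum(|z1_i - z2_i|) / w`, computed over the `w` columns where both are
#' defined.
#'
#' @param b1,b2 [oct_boundary] objects of the same width.
#' @return Mean absolute difference in pixels.
#' @export
unsigned_error <- function(b1, b2) {
  if (length(b1$z) != length(b2$z))
    .lw_stop("boundaries have different widths")
  cols <- .common_cols(b1, b2)
  if (!length(cols))
    .lw_stop("boundaries share no defined columns")
  mean(abs(b1$z[cols] - b2$z[cols]))
}

#' Gold-standard boundary by averaging graders
#'
#' Pointwise mean depth per column over the columns where every input is
#' defined; the conventional construction of a reference trace from several
#' graders' delineations.
#'
#' @param boundaries list of two or more [oct_boundary] objects sharing a
#'   label and width.
#' @return The averaged [oct_boundary].
#' @export
make_gold <- function(boundaries) {
  if (length(boundaries) < 2L) .lw_stop("need at least 2 boundaries")
  labs <- unique(vapply(boundaries, `[[`, character(1), "label"))
  if (length(labs) != 1L)
    .lw_stop("boundaries have mismatched labels: ",
             paste(labs, collapse = ", "))
  zmat <- do.call(rbind, lapply(boundaries, `[[`, "z"))
  def <- Reduce(`&`, lapply(boundaries, `[[`, "defined"))
  if (!any(def)) .lw_stop("no common defined range")
  z <- colMeans(zmat)
  z[!def] <- NA_real_
  oct_boundary(labs, z)
}

#' Boundary irregularity index
#'
#' Chord-to-arc ratio `L_r / L_b`: `L_r` is the Euclidean distance between
#' the first and last defined points, `L_b` the polyline length
#' `sum(sqrt(1 + dz^2))` along the defined range. A perfectly straight
#' boundary scores 1; deformation drives the value toward 0. Set
#' `inverse = TRUE` to report `L_b / L_r` (arc-to-chord) instead.
#'
#' @param b an [oct_boundary] defined on at least 2 consecutive columns.
#' @param inverse report the reciprocal convention.
#' @return Dimensionless ratio in (0, 1\] (or \[1, Inf) when `inverse`).
#' @export
irregularity_index <- function(b, inverse = FALSE) {
  cols <- which(b$defined)
  if (length(cols) < 2L)
    .lw_stop("irregularity index needs >= 2 defined columns")
  x <- cols - 1L; z <- b$z[cols]
  n <- length(x)
  l_r <- sqrt((x[n] - x[1L])^2 + (z[n] - z[1L])^2)
  l_b <- sum(sqrt(diff(x)^2 + diff(z)^2))
  if (inverse) l_b / l_r else l_r / l_b
}

#' Dice overlap coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)` over the true pixels of two binary
#' masks. Two empty masks are defined to agree perfectly (Dice 1); an empty
#' versus a non-empty mask scores 0.
#'
#' @param m1,m2 logical matrices or [fluid_mask] objects of the same shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(m1, m2) {
  a <- if (inherits(m1, "fluid_mask")) m1$mask else m1
  b <- if (inherits(m2, "fluid_mask")) m2$mask else m2
  if (!all(dim(a) == dim(b))) .lw_stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Bland-Altman agreement summary
#'
#' Paired differences `d = a - b`; bias is `mean(d)`, the 95% limits of
#' agreement are `bias +/- 1.96 sd(d)` (sd with denominator n-1), and
#' `pct_within` is the percentage of differences falling inside the limits.
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return A list of class `bland_altman` with `bias`, `loa_low`,
#'   `loa_high`, `pct_within`, `n` and the differences `d`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) .lw_stop("inputs must have equal length")
  if (length(a) < 2L) .lw_stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  structure(list(bias = bias, loa_low = lo, loa_high = hi,
                 pct_within = 100 * mean(d >= lo & d <= hi),
                 n = length(d), d = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman: n %d, bias %.4g px, LoA [%.4g, %.4g], %.1f%% within>\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$pct_within))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against pair means with the bias and 95%
#' limits of agreement drawn as horizontal lines.
#'
#' @param ba a `bland_altman` summary.
#' @param a,b the paired measurements the summary came from.
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(ba, a, b, path, main = "Bland-Altman") {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::plot((a + b) / 2, a - b, pch = 16, cex = 0.6,
                 xlab = "mean of pair", ylab = "difference", main = main)
  graphics::abline(h = c(ba$loa_low, ba$bias, ba$loa_high),
                   lty = c(2, 1, 2), col = c("red", "black", "red"))
  invisible(path)
}

#' Repeatability report between two segmentation runs
#'
#' Matches boundaries by (id, label) and masks by id, then reports the
#' per-label mean unsigned error and per-scan Dice, with overall means.
#' Unmatched entries are listed, excluded and warned about.
#'
#' @param run1,run2 lists with elements `boundaries` (named list
#'   `[[id]][[label]]` of [oct_boundary]) and/or `masks` (named list
#'   `[[id]]` of [fluid_mask] or logical matrix).
#' @return A list of class `repeatability_report` with data frames
#'   `boundary_errors` (label, n, mean_unsigned_error), `mask_dice`
#'   (id, dice), scalars `overall_unsigned_error`, `overall_dice`, and
#'   `unmatched`.
#' @export
repeatability_report <- function(run1, run2) {
  unmatched <- character(0)
  errs <- list()
  b1 <- run1$boundaries %||% list()
  b2 <- run2$boundaries %||% list()
  for (id in union(names(b1), names(b2))) {
    for (lab in union(names(b1[[id]]), names(b2[[id]]))) {
      u <- b1[[id]][[lab]]; v <- b2[[id]][[lab]]
      if (is.null(u) || is.null(v)) {
        unmatched <- c(unmatched, paste0(id, "/", lab))
      } else {
        errs[[length(errs) + 1L]] <-
          data.frame(id = id, label = lab, err = unsigned_error(u, v))
      }
    }
  }
  be <- if (length(errs)) {
    df <- do.call(rbind, errs)
    agg <- aggregate(err ~ label, df, mean)
    cnt <- aggregate(err ~ label, df, length)
    data.frame(label = agg$label, n = cnt$err,
               mean_unsigned_error = agg$err)
  } else data.frame(label = character(), n = integer(),
                    mean_unsigned_error = numeric())
  m1 <- run1$masks %||% list(); m2 <- run2$masks %||% list()
  dd <- list()
  for (id in union(names(m1), names(m2))) {
    if (is.null(m1[[id]]) || is.null(m2[[id]]))
      unmatched <- c(unmatched, paste0(id, "/mask"))
    else dd[[length(dd) + 1L]] <- data.frame(id = id,
                                             dice = dice(m1[[id]], m2[[id]]))
  }
  md <- if (length(dd)) do.call(rbind, dd)
        else data.frame(id = character(), dice = numeric())
  if (length(unmatched))
    .lw_warn("unmatched entries excluded from report: ",
             paste(unmatched, collapse = ", "))
  structure(list(
    boundary_errors = be, mask_dice = md,
    overall_unsigned_error = if (nrow(be)) mean(be$mean_unsigned_error)
                             else NA_real_,
    overall_dice = if (nrow(md)) mean(md$dice) else NA_real_,
    unmatched = unmatched), class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat("<repeatability_report>\n")
  if (nrow(x$boundary_errors)) {
    print(x$boundary_errors, row.names = FALSE)
    cat(sprintf("overall mean unsigned error: %.4g px\n",
                x$overall_unsigned_error))
  }
  if (nrow(x$mask_dice)) {
    print(x$mask_dice, row.names = FALSE)
    cat(sprintf("overall Dice: %.4g\n", x$overall_dice))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
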