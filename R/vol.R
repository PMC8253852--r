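# Spectralis VOL (HSF dialect) reader. Only the fields this pipeline needs
# are interpreted: lattice sizes, physical scales, scan position and the
# per-B-scan float32 pixel blocks; the SLO image and the per-B-scan headers
# are seeked past using the offsets recorded in the file header.

.VOL_MAGIC <- "HSF-OCT-"
.VOL_HEADER_SIZE <- 2048L

#' Read a Spectralis VOL volume
#'
#' Parses the HSF-OCT container: a fixed 2048-byte header (version magic,
#' `SizeX`, `NumBScans`, `SizeZ`, scales, SLO geometry, scan position,
#' `BScanHdrSize`), a fundus (SLO) block that is skipped, and per-B-scan
#' blocks of `SizeX * SizeZ` float32 raw reflectivities. Raw values are
#' mapped to display intensities by the conventional fourth-root transform
#' (`clip(raw, 0, 1)^(1/4)`); raw values at or above 1e38 mark missing data
#' and become 0.
#'
#' @param path path to a `.vol` file.
#' @return An [oct_volume] with `source_format = "vol"`; each B-scan carries
#'   `scale_x` and `scale_z` in mm/pixel.
#' @export
read_vol <- function(path) {
  if (!file.exists(path)) .lw_stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, .VOL_MAGIC))
    .lw_stop("not a VOL file (missing HSF-OCT magic): ", path)
  readBin(con, "raw", 4L)                      # rest of the 12-byte version
  size_x     <- readBin(con, "integer", 1L, size = 4L)
  num_bscans <- readBin(con, "integer", 1L, size = 4L)
  size_z     <- readBin(con, "integer", 1L, size = 4L)
  scale_x    <- readBin(con, "double", 1L, size = 8L)
  readBin(con, "double", 1L, size = 8L)        # Distance (between B-scans)
  scale_z    <- readBin(con, "double", 1L, size = 8L)
  size_x_slo <- readBin(con, "integer", 1L, size = 4L)
  size_y_slo <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "double", 2L, size = 8L)        # SLO scales
  readBin(con, "integer", 1L, size = 4L)       # FieldSizeSlo
  readBin(con, "double", 1L, size = 8L)        # ScanFocus
  scan_pos <- rawToChar(readBin(con, "raw", 4L))
  readBin(con, "raw", 8L)                      # ExamTime
  readBin(con, "integer", 1L, size = 4L)       # ScanPattern
  bscan_hdr_size <- readBin(con, "integer", 1L, size = 4L)
  if (any(c(size_x, num_bscans, size_z, bscan_hdr_size) <= 0) ||
      size_x_slo < 0 || size_y_slo < 0)
    .lw_stop("garbled VOL header in ", path)

  eye <- if (startsWith(scan_pos, "OD")) "OD"
         else if (startsWith(scan_pos, "OS")) "OS" else "unknown"

  seek(con, .VOL_HEADER_SIZE + as.numeric(size_x_slo) * size_y_slo)
  bscans <- vector("list", num_bscans)
  for (i in seq_len(num_bscans)) {
    readBin(con, "raw", bscan_hdr_size)
    n <- size_x * size_z
    raw <- readBin(con, "double", n, size = 4L)
    if (length(raw) != n)
      .lw_stop("truncated VOL pixel block at B-scan ", i, " in ", path)
    raw[!is.finite(raw) | raw >= 1e38] <- 0
    disp <- pmin(pmax(raw, 0), 1)^0.25
    # block is stored row-major by depth: SizeX values per depth row
    px <- matrix(disp, nrow = size_z, ncol = size_x, byrow = TRUE)
    bscans[[i]] <- bscan(.as_unit_interval(px), scale_x = scale_x,
                         scale_z = scale_z,
                         id = sprintf("bscan_%03d", i - 1L))
  }
  oct_volume(bscans, eye = eye, source_format = "vol")
}

#' Write a minimal VOL fixture
#'
#' Produces a file in the same HSF dialect [read_vol] consumes, for tests
#' and round-trip validation: display-domain matrices in \[0, 1\] are stored
#' as float32 raw reflectivities (`display^4`), with a small blank SLO block
#' and blank per-B-scan headers.
#'
#' @param pixels_list list of numeric matrices in \[0, 1\] sharing dimensions
#'   (rows = depth).
#' @param path output path.
#' @param scale_x,scale_z mm/pixel written to the header.
#' @param eye `"OD"` or `"OS"`.
#' @param slo_size edge length of the dummy SLO block (pixels).
#' @return `path`, invisibly.
#' @export
write_vol_fixture <- function(pixels_list, path, scale_x = 0.0117,
                              scale_z = 0.0039, eye = "OD", slo_size = 16L) {
  stopifnot(length(pixels_list) >= 1L)
  h <- nrow(pixels_list[[1L]]); w <- ncol(pixels_list[[1L]])
  bscan_hdr_size <- 256L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("HSF-OCT-103"), as.raw(0L)), con)
  writeBin(as.integer(c(w, length(pixels_list), h)), con, size = 4L)
  writeBin(as.numeric(c(scale_x, 0.12, scale_z)), con, size = 8L)
  writeBin(as.integer(c(slo_size, slo_size)), con, size = 4L)
  writeBin(as.numeric(c(0.03, 0.03)), con, size = 8L)   # SLO scales
  writeBin(0L, con, size = 4L)                          # FieldSizeSlo
  writeBin(0.0, con, size = 8L)                         # ScanFocus
  writeBin(charToRaw(sprintf("%-4s", substr(eye, 1, 3))), con)
  writeBin(raw(8L), con)                                # ExamTime
  writeBin(0L, con, size = 4L)                          # ScanPattern
  writeBin(bscan_hdr_size, con, size = 4L)
  pos <- 12L + 3L * 4L + 3L * 8L + 2L * 4L + 2L * 8L + 4L + 8L + 4L + 8L +
    4L + 4L
  writeBin(raw(.VOL_HEADER_SIZE - pos), con)            # header padding
  writeBin(raw(slo_size * slo_size), con)               # blank SLO
  for (px in pixels_list) {
    stopifnot(nrow(px) == h, ncol(px) == w)
    writeBin(raw(bscan_hdr_size), con)
    raw_vals <- as.numeric(t(pmin(pmax(px, 0), 1)^4))   # row-major by depth
    writeBin(raw_vals, con, size = 4L)
  }
  invisible(path)
}
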