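test_that("VOL fixture roundtrip preserves geometry and pixels", {
  set.seed(1)
  mats <- replicate(3, matrix(runif(40 * 32), 40, 32), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".vol")
  write_vol_fixture(mats, path, scale_x = 0.0117, scale_z = 0.0039,
                    eye = "OS")
  vol <- read_vol(path)
  expect_equal(vol$num_bscans, 3L)
  expect_equal(vol$eye, "OS")
  expect_equal(vol$bscans[[1]]$width, 32L)
  expect_equal(vol$bscans[[1]]$height, 40L)
  expect_equal(vol$bscans[[1]]$scale_x, 0.0117)
  for (i in 1:3)
    expect_equal(vol$bscans[[i]]$pixels, mats[[i]], tolerance = 1e-6)
})

test_that("VOL reader reports study-scale geometry from the header", {
  mats <- replicate(61, matrix(0.5, 8, 512), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".vol")
  write_vol_fixture(mats, path)
  vol <- read_vol(path)
  expect_equal(vol$num_bscans, 61L)
  expect_equal(vol$bscans[[1]]$width, 512L)
})

test_that("VOL reader rejects bad files with precise errors", {
  empty <- withr::local_tempfile(fileext = ".vol")
  file.create(empty)
  expect_error(read_vol(empty), "magic")
  expect_error(read_vol(withr::local_tempfile()), "not found")
  # truncate the last pixel block
  mats <- replicate(2, matrix(0.5, 10, 12), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".vol")
  write_vol_fixture(mats, path)
  sz <- file.size(path)
  con <- file(path, "r+b"); truncate_at <- sz - 100
  seek(con, truncate_at); truncate(con); close(con)
  expect_error(read_vol(path), "B-scan 2")
})

test_that("image stacks are normalized per image with the zero-range rule", {
  d <- withr::local_tempdir()
  set.seed(2)
  m1 <- matrix(runif(496 * 512, 0.2, 0.8), 496, 512)
  png::writePNG(m1, file.path(d, "a.png"))
  png::writePNG(matrix(0.5, 496, 512), file.path(d, "b.png"))
  vol <- read_image_stack(file.path(d, c("a.png", "b.png")))
  expect_equal(vol$num_bscans, 2L)
  expect_equal(min(vol$bscans[[1]]$pixels), 0)
  expect_equal(max(vol$bscans[[1]]$pixels), 1)
  expect_true(all(vol$bscans[[2]]$pixels == 0))   # constant image -> 0
  png::writePNG(matrix(0.5, 10, 10), file.path(d, "c.png"))
  expect_error(read_image_stack(file.path(d, c("a.png", "c.png"))), "c.png")
})

test_that("phantom PNG roundtrip stays within 8-bit quantization", {
  ph <- generate_bscan(phantom_spec(height = 96, width = 128, ilm_depth = 20,
    thickness = c(NFL = 5, GCL = 6, IPL = 6, INL = 5, OPL = 5, ONL = 12,
                  PR = 5, RPE = 4),
    fovea = NULL, speckle_sigma = 0.02, seed = 9))
  path <- withr::local_tempfile(fileext = ".png")
  # pre-stretch to [0, 1] so the reader's min-max rescale is the identity
  # and only 8-bit quantization remains
  px <- ph$image$pixels
  px <- (px - min(px)) / (max(px) - min(px))
  png::writePNG(px, path)
  back <- read_image_stack(path)$bscans[[1]]
  expect_lt(max(abs(back$pixels - px)), 1 / 255)
})

test_that("boundary CSV roundtrip is lossless at 6 decimals", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_boundaries_csv(list(), path)
  expect_equal(length(read_boundaries_csv(path)), 0L)
  expect_equal(length(readLines(path)), 1L)       # header only
  b1 <- random_boundary(5, 1, label = "ILM")
  b2 <- random_boundary(5, 2, label = "OPL_ONL")
  write_boundaries_csv(list(b1, b2), path, bscan_id = "s1")
  expect_equal(length(readLines(path)), 11L)      # header + 2 * 5 rows
  back <- read_boundaries_csv(path)$s1
  expect_lte(max(abs(back$ILM$z - b1$z)), 5e-7)
  expect_lte(max(abs(back$OPL_ONL$z - b2$z)), 5e-7)
  # unknown label text rejected
  writeLines(c("bscan_id,label,x,z,defined", "s1,NOT_A_LAYER,0,1.0,TRUE"),
             path)
  expect_error(read_boundaries_csv(path), "NOT_A_LAYER")
})

test_that("partially defined boundaries survive the CSV roundtrip", {
  z <- c(NA, NA, 10.5, 11.25, 12, NA)
  b <- oct_boundary("ILM", z)
  path <- withr::local_tempfile(fileext = ".csv")
  write_boundaries_csv(list(b), path, bscan_id = "s1")
  back <- read_boundaries_csv(path)$s1$ILM
  expect_equal(back$defined, !is.na(z))
  expect_equal(back$z[3:5], z[3:5])
})

test_that("anchor CSV roundtrips open and closed groups", {
  a_open <- anchor_seq(c(0, 10, 30), c(5, 6, 7))
  a_closed <- list(anchor_seq(c(3, 9, 6), c(2, 4, 8), mode = "closed"),
                   anchor_seq(c(20, 26, 23), c(2, 4, 8), mode = "closed"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_anchors_csv(list(s1 = list(ILM = a_open, OPL_ONL = a_closed)), path)
  back <- read_anchors_csv(path)
  expect_identical(back$s1$ILM$x, a_open$x)
  expect_identical(back$s1$ILM$mode, "open")
  expect_length(back$s1$OPL_ONL, 2L)
  expect_identical(back$s1$OPL_ONL[[2]]$z, a_closed[[2]]$z)
})

test_that("overlays place palette colours on the drawn boundaries", {
  ph <- two_band_image()
  path <- withr::local_tempfile(fileext = ".png")
  # no boundaries, no mask: grayscale replica
  write_overlay(ph, list(), path = path)
  arr <- png::readPNG(path)
  expect_equal(arr[, , 1], arr[, , 2])
  expect_lt(max(abs(arr[, , 1] - ph$pixels)), 1 / 255)
  # one flat boundary at z = 10 colours row 10
  b <- oct_boundary("ILM", rep(10, ph$width))
  write_overlay(ph, list(b), path = path)
  arr <- png::readPNG(path)
  expect_true(all(abs(arr[11, , 1] - 1.0) < 2 / 255))     # ILM palette red
  expect_true(all(arr[11, , 3] < 0.2))
  expect_error(write_overlay(ph, list(oct_boundary("ILM", rep(1, 7))),
                             path = path), "width")
})

test_that("ground-truth overlay pixels carry the boundary colour", {
  ph <- generate_bscan(phantom_spec(seed = 4))
  path <- withr::local_tempfile(fileext = ".png")
  write_overlay(ph$image, ph$boundaries["ILM"], path = path)
  arr <- png::readPNG(path)
  gt <- ph$boundaries$ILM
  for (x in seq(1, 512, by = 10)) {
    r <- floor(gt$z[x] + 0.5) + 1
    expect_equal(arr[r, x, 1], 1.0, tolerance = 2 / 255)
  }
})
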