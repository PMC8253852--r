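peri_spec <- function(seed, vessels = NULL, amplitude = 25, fovea = NULL) {
  phantom_spec(seed = seed, fovea = fovea,
               curvature = if (amplitude > 0)
                 list(amplitude = amplitude, period = 450),
               vessels = vessels)
}

test_that("reference estimation tracks the bright outer band", {
  ph <- generate_bscan(peri_spec(2))
  ref <- estimate_reference_boundary(ph$image)
  expect_true(all(ref$defined))
  # the estimator locks onto the brightest outer complex; its curve must
  # follow the generator's curvature (constant offset allowed)
  d <- ref$z - ph$boundaries$PR_RPE$z
  expect_lt(stats::sd(d), 2)
  # degenerate constant image still yields a defined, smooth boundary
  flat <- bscan(matrix(0.3, 60, 40))
  rf <- estimate_reference_boundary(flat)
  expect_true(all(rf$defined))
  expect_equal(length(unique(rf$z)), 1L)
})

test_that("equal-maxima columns resolve to the smaller depth", {
  px <- matrix(0, 50, 20)
  px[31, ] <- 1; px[41, ] <- 1          # two equal peaks in the lower 60%
  ref <- estimate_reference_boundary(bscan(px))
  expect_true(all(ref$z <= 31))
})

test_that("shift vectors realize max-minus-z with a zero minimum", {
  expect_equal(as.integer(compute_shift_vector(
    oct_boundary("ONL_PR", rep(12, 5)))), rep(0L, 5))
  s <- compute_shift_vector(oct_boundary("ONL_PR", c(10, 12, 15)))
  expect_equal(as.integer(s), c(5L, 3L, 0L))
  for (seed in 1:5) {
    ref <- random_boundary(30, seed, label = "ONL_PR", base = 100)
    s <- compute_shift_vector(ref)
    expect_equal(min(s), 0L)
    expect_equal(unname(round(ref$z) + s), rep(max(round(ref$z)), 30),
                 tolerance = 1)
  }
  expect_error(compute_shift_vector(oct_boundary("ONL_PR", c(1, NA, 3))),
               "all columns")
})

test_that("flatten and unflatten are exact inverses", {
  set.seed(8)
  img <- bscan(matrix(runif(40 * 25), 40, 25))
  expect_identical(flatten(img, rep(0L, 25))$pixels, img$pixels)
  for (rep in 1:5) {
    s <- sample(0:39, 25, replace = TRUE)
    expect_identical(unflatten(flatten(img, s), s)$pixels, img$pixels)
  }
  expect_error(flatten(img, rep(0L, 10)), "length")
})

test_that("flattening with the computed shift levels the reference", {
  ph <- generate_bscan(peri_spec(6))
  ref <- estimate_reference_boundary(ph$image)
  s <- compute_shift_vector(ref)
  flat_ref <- ref$z + s
  expect_lte(max(flat_ref) - min(flat_ref), 1)    # constant up to rounding
})

test_that("vessel shadows are detected at their true columns", {
  centers <- c(100, 220, 400)
  ph <- generate_bscan(peri_spec(3, vessels = data.frame(
    center_x = centers, width = 8, darkening = 0.3)))
  ref <- estimate_reference_boundary(ph$image)
  s <- compute_shift_vector(ref)
  flat <- flatten(ph$image, s)
  ipl <- oct_boundary("IPL_INL", pmin(ph$boundaries$IPL_INL$z + s, 495))
  vs <- detect_vessels(flat, ipl)
  expect_equal(nrow(vs), 3L)
  expect_true(all(abs(vs$center_x - centers) <= 1))
  # raising the threshold above the shadow depth empties the set
  none <- detect_vessels(flat, ipl, min_prominence = 0.5)
  expect_equal(nrow(none), 0L)
  # constant image: no vessels
  expect_equal(nrow(detect_vessels(bscan(matrix(0.5, 60, 40)),
                                   oct_boundary("IPL_INL", rep(10, 40)))),
               0L)
})

test_that("vessel removal flattens the shadow profile and is local", {
  ph <- generate_bscan(peri_spec(9, amplitude = 0, vessels = data.frame(
    center_x = c(150, 350), width = 8, darkening = 0.35)))
  img <- ph$image
  ipl <- ph$boundaries$IPL_INL
  vs <- detect_vessels(img, ipl)
  expect_equal(nrow(vs), 2L)
  fixed <- remove_vessels(img, vs)
  col_mean <- function(b, x) mean(b$pixels[200:496, x])
  prof_before <- vapply(140:160, function(x) col_mean(img, x), numeric(1))
  prof_after <- vapply(140:160, function(x) col_mean(fixed, x), numeric(1))
  expect_lt(stats::sd(prof_after), 0.3 * stats::sd(prof_before))
  # untouched columns are bit-identical
  touched <- unlist(lapply(seq_len(nrow(vs)), function(i)
    (vs$center_x[i] - vs$half_width[i]):(vs$center_x[i] + vs$half_width[i])))
  keep <- setdiff(0:511, touched)
  expect_identical(fixed$pixels[, keep + 1], img$pixels[, keep + 1])
  # empty set: identity
  expect_identical(remove_vessels(img, vs[0, ])$pixels, img$pixels)
})

test_that("edge-touching vessels fall back to one-sided copies", {
  ph <- generate_bscan(peri_spec(10, amplitude = 0, vessels = data.frame(
    center_x = 4, width = 6, darkening = 0.4)))
  vs <- data.frame(center_x = 4L, half_width = 4L, prominence = 0.1)
  expect_warning(out <- remove_vessels(ph$image, vs), "one-sided")
  expect_identical(out$pixels[, 10:512], ph$image$pixels[, 10:512])
})

test_that("full peripapillary pipeline recovers all 8 boundaries", {
  ph <- generate_bscan(peri_spec(5, vessels = data.frame(
    center_x = c(100, 220, 400), width = 8, darkening = 0.3)))
  ref <- estimate_reference_boundary(ph$image)
  s <- compute_shift_vector(ref)
  anchors <- lapply(PERIPAPILLARY_LABELS, function(lab)
    simulate_clicks(oct_boundary(lab, ph$boundaries[[lab]]$z + s), 6,
                    jitter_sigma = 1, seed = 50 + nchar(lab), height = 496))
  names(anchors) <- PERIPAPILLARY_LABELS
  res <- segment_peripapillary(ph$image, anchors)
  for (lab in PERIPAPILLARY_LABELS)
    expect_lt(unsigned_error(res$boundaries[[lab]], ph$boundaries[[lab]]),
              2, label = paste("unsigned error", lab))
  expect_error(
    segment_peripapillary(ph$image, c(anchors, list(GCL_IPL = anchors[[1]]))),
    "GCL_IPL")
})

test_that("zero-curvature scans reduce to the macular result", {
  # noiseless flat phantom: the reference estimate is constant, the shift
  # vector zero, flattening the identity -- the two modes must coincide
  sp <- phantom_spec(seed = 12, fovea = NULL, speckle_sigma = 0)
  ph <- generate_bscan(sp)
  ref <- estimate_reference_boundary(ph$image)
  s <- compute_shift_vector(ref)
  expect_true(all(s == 0L))
  expect_identical(flatten(ph$image, s)$pixels, ph$image$pixels)
  a <- list(ILM = simulate_clicks(ph$boundaries$ILM, 5, 1, seed = 12,
                                  height = 496))
  res <- segment_peripapillary(ph$image, a)
  mac <- segment_macular(ph$image, a)
  expect_equal(res$boundaries$ILM$z, mac$ILM$z)
})
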