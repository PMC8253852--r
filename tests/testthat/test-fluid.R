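ellipse_spec <- function(seed, cx = 180, cz = 270, ax = 35, az = 22) {
  phantom_spec(seed = seed, fovea = NULL,
               fluids = data.frame(center_x = cx, center_z = cz, ax = ax,
                                   az = az, intensity = 0.02))
}

test_that("fluid backgrounds are uniform on featureless images", {
  bg <- fluid_background(bscan(matrix(0.5, 40, 40)))
  expect_equal(max(bg$cost), min(bg$cost))
  expect_gte(min(bg$cost), bg$eps)
})

test_that("the ellipse rim is a cheap ridge of the fluid background", {
  # dark ellipse on a uniform bright band: the rim is the only edge
  h <- 120; w <- 160
  zz <- matrix(0:(h - 1), h, w); xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  cx <- 80; cz <- 60; ax <- 35; az <- 22
  px <- matrix(0.7, h, w)
  px[((xx - cx) / ax)^2 + ((zz - cz) / az)^2 <= 1] <- 0.05
  bg <- fluid_background(bscan(px, id = "ellipse"))
  for (ang in seq(0, 2 * pi, length.out = 17)[-17]) {
    # scan the cost along the ray through this rim angle
    ts <- seq(0.7, 1.3, by = 0.01)
    rx <- round(cx + ts * ax * cos(ang))
    rz <- round(cz + ts * az * sin(ang))
    costs <- bg$cost[cbind(rz + 1, rx + 1)]
    t_min <- ts[which.min(costs)]
    # minimal cost within ~1 px of the true rim (t = 1)
    r_ang <- sqrt((ax * cos(ang))^2 + (az * sin(ang))^2)
    expect_lt(abs(t_min - 1) * r_ang, 1.6)
  }
})

test_that("closing radius 0 leaves the edge set unchanged", {
  ph <- generate_bscan(ellipse_spec(22))
  e <- edge_canny(ph$image)
  bg0 <- fluid_background(ph$image, close_radius = 0)
  expect_true(all(bg0$cost[e] == bg0$eps))
})

test_that("closed contours follow a zero-cost square ring exactly", {
  m <- matrix(1, 30, 30)
  m[6:15, 6] <- 1e-6; m[6:15, 15] <- 1e-6
  m[6, 6:15] <- 1e-6; m[15, 6:15] <- 1e-6
  ci <- cost_image(m, eps = 1e-6)
  a <- anchor_seq(c(5, 14, 14, 5), c(5, 5, 14, 14), mode = "closed")
  ct <- trace_closed_contour(ci, a)
  on_ring <- ct$z == 5 | ct$z == 14 | ct$x == 5 | ct$x == 14
  expect_true(all(on_ring))
  expect_equal(ct$n, 36L)               # perimeter of the 10x10 ring
  # reversing the anchor order yields the same pixel set
  ar <- anchor_seq(rev(c(5, 14, 14, 5)), rev(c(5, 5, 14, 14)),
                   mode = "closed")
  ctr <- trace_closed_contour(ci, ar)
  expect_setequal(paste(ct$x, ct$z), paste(ctr$x, ctr$z))
})

test_that("rasterization matches analytic areas and the even-odd oracle", {
  sq <- polygon_cycle(c(5, 14, 14, 5), c(5, 5, 14, 14))
  m <- rasterize_mask(sq, c(25, 25))
  expect_equal(sum(m$mask), 100L)               # 10 x 10 square
  thin <- polygon_cycle(c(3, 12), c(8, 8))      # 1-px-wide degenerate
  mt <- rasterize_mask(thin, c(25, 25))
  expect_equal(sum(mt$mask), 10L)
  # random star polygons against a brute-force point-in-polygon scan
  set.seed(13)
  for (rep in 1:5) {
    nv <- 10L
    angs <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
    rad <- ifelse(seq_len(nv) %% 2 == 0, 18, runif(nv, 7, 10))
    vx <- round(30 + rad * cos(angs)); vz <- round(30 + rad * sin(angs))
    star <- polygon_cycle(vx, vz)
    got <- rasterize_mask(star, c(60, 60))$mask
    grid <- expand.grid(z = 0:59, x = 0:59)
    oracle <- matrix(point_in_polygon(grid$x, grid$z, vx, vz), 60, 60)
    ring <- matrix(FALSE, 60, 60)
    ring[cbind(star$z + 1, star$x + 1)] <- TRUE
    # away from the discretized ring the two fills must agree exactly
    near_ring <- as.matrix(EBImage::dilate(ring * 1,
                                           EBImage::makeBrush(5, "box"))) > 0
    expect_identical(got[!near_ring], oracle[!near_ring])
    # and the total areas agree to within the ring pixels themselves
    expect_lt(abs(sum(got) - sum(oracle | ring)), sum(ring))
  }
})

test_that("component bookkeeping partitions the mask", {
  m <- matrix(FALSE, 30, 30)
  m[2:6, 2:3] <- TRUE                    # area 10
  m[15:20, 10:19] <- TRUE                # area 60
  fm <- fluid_mask(m)
  expect_equal(nrow(fm$components), 2L)
  expect_equal(sum(fm$components$area), sum(fm$mask))
  f <- filter_small_objects(fm, 50)
  expect_equal(nrow(f$components), 1L)
  expect_equal(f$components$area, 60L)
  expect_identical(filter_small_objects(fm, 0)$mask, fm$mask)
  empty <- filter_small_objects(fm, 1000)
  expect_equal(sum(empty$mask), 0L)
  # monotonicity: raising min_area never increases the component count
  counts <- vapply(c(0, 5, 10, 11, 60, 61),
                   function(a) nrow(filter_small_objects(fm, a)$components),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("traced ellipse masks recover the ground truth", {
  ph <- generate_bscan(ellipse_spec(25))
  a <- simulate_fluid_clicks(ph$fluid, 1, 5, seed = 25)
  ct <- trace_closed_contour(fluid_background(ph$image), a)
  m <- rasterize_mask(ct, c(496, 512))
  expect_gt(dice(m, ph$fluid), 0.85)
})

test_that("rim-anchored tracing recovers the area of a clean ellipse", {
  h <- 120; w <- 160
  zz <- matrix(0:(h - 1), h, w); xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  px <- matrix(0.7, h, w)
  inside <- ((xx - 80) / 35)^2 + ((zz - 60) / 22)^2 <= 1
  px[inside] <- 0.05
  gt <- fluid_mask(inside)
  a <- simulate_fluid_clicks(gt, 1, 5, seed = 3)
  ct <- trace_closed_contour(fluid_background(bscan(px)), a)
  m <- rasterize_mask(ct, c(h, w))
  expect_lt(abs(sum(m$mask) - sum(inside)) / sum(inside), 0.05)
  expect_gt(dice(m, gt), 0.9)
})
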