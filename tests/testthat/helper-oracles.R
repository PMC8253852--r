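# Independent oracles and fixture builders used across the suite.

# Bellman-Ford shortest path on the same 8-connected grid graph: an
# implementation-independent check of the Dijkstra tracer's total cost.
bellman_ford_cost <- function(cost, src, dst) {
  h <- nrow(cost); w <- ncol(cost)
  id <- function(z, x) (x - 1L) * h + z          # 1-based grid index
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (z in 1:h) for (x in 1:w) {
    for (d in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                   c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
      nz <- z + d[1L]; nx <- x + d[2L]
      if (nz < 1L || nz > h || nx < 1L || nx > w) next
      from <- c(from, id(z, x)); to <- c(to, id(nz, nx))
      wt <- c(wt, ((cost[z, x] + cost[nz, nx]) / 2) *
                if (all(d != 0L)) sqrt(2) else 1)
    }
  }
  dist <- rep(Inf, h * w)
  dist[id(src[2L] + 1L, src[1L] + 1L)] <- 0
  for (k in seq_len(h * w - 1L)) {
    cand <- dist[from] + wt
    o <- order(to, cand)
    first <- !duplicated(to[o])
    nd <- dist
    nd[to[o][first]] <- pmin(dist[to[o][first]], cand[o][first])
    if (identical(nd, dist)) break
    dist <- nd
  }
  dist[id(dst[2L] + 1L, dst[1L] + 1L)]
}

# even-odd point-in-polygon scan (ray casting on pixel centres)
point_in_polygon <- function(px, pz, vx, vz) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in 1:n) {
    cross <- (vz[i] > pz) != (vz[j] > pz)
    xint <- (vx[j] - vx[i]) * (pz - vz[i]) / (vz[j] - vz[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

# 8-connected Bresenham segment between two pixels (inclusive)
bresenham <- function(x0, z0, x1, z1) {
  dx <- abs(x1 - x0); dz <- abs(z1 - z0)
  sx <- sign(x1 - x0); sz <- sign(z1 - z0)
  err <- dx - dz
  xs <- integer(0); zs <- integer(0)
  repeat {
    xs <- c(xs, x0); zs <- c(zs, z0)
    if (x0 == x1 && z0 == z1) break
    e2 <- 2L * err
    if (e2 > -dz) { err <- err - dz; x0 <- x0 + sx }
    if (e2 < dx) { err <- err + dx; z0 <- z0 + sz }
  }
  list(x = xs, z = zs)
}

# closed 8-connected pixel cycle through polygon vertices
polygon_cycle <- function(vx, vz) {
  xs <- integer(0); zs <- integer(0)
  n <- length(vx)
  for (i in 1:n) {
    j <- if (i == n) 1L else i + 1L
    seg <- bresenham(vx[i], vz[i], vx[j], vz[j])
    keep <- seq_len(length(seg$x) - 1L)
    xs <- c(xs, seg$x[keep]); zs <- c(zs, seg$z[keep])
  }
  structure(list(x = xs, z = zs, total_cost = 0, n = length(xs)),
            class = "pixel_path")
}

random_cost_grid <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w, 0.05, 1), h, w)
}

random_boundary <- function(width, seed, label = "ILM", base = 50) {
  set.seed(seed)
  z <- base + cumsum(rnorm(width, 0, 0.5))
  oct_boundary(label, z)
}

# a two-band image: dark above row r, bright below (0-based r)
two_band_image <- function(h = 60, w = 40, r = 25, lo = 0.1, hi = 0.8) {
  px <- matrix(lo, h, w)
  px[(r + 1L):h, ] <- hi
  bscan(px, id = "two_band")
}

# uniform-cost image with one near-zero-cost ridge row
ridge_cost <- function(h = 30, w = 50, r = 12, eps = 1e-6) {
  m <- matrix(1, h, w)
  m[r + 1L, ] <- eps
  cost_image(m, eps = eps)
}
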