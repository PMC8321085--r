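# Independent oracles used across the suite. These deliberately share no code
# with the package: plain loops, textbook formulas.

# trilinear interpolation of a 3D array at a world point (plain loops)
oracle_trilinear <- function(data, spacing, p) {
  idx <- p / spacing
  lo <- pmin(pmax(floor(idx), 0), dim(data) - 1)
  hi <- pmin(lo + 1, dim(data) - 1)
  f <- idx - lo
  f <- pmin(pmax(f, 0), 1)
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    i <- if (dx == 0) lo[1] else hi[1]
    j <- if (dy == 0) lo[2] else hi[2]
    k <- if (dz == 0) lo[3] else hi[3]
    w <- (if (dx == 0) 1 - f[1] else f[1]) *
         (if (dy == 0) 1 - f[2] else f[2]) *
         (if (dz == 0) 1 - f[3] else f[3])
    v <- v + w * data[i + 1, j + 1, k + 1]
  }
  v
}

# piecewise-linear ramp lookup with clamping (textbook, no approx())
oracle_ramp <- function(pts, x) {
  n <- nrow(pts)
  out <- numeric(length(x))
  for (q in seq_along(x)) {
    v <- x[q]
    if (v <= pts[1, 1]) { out[q] <- pts[1, 2]; next }
    if (v >= pts[n, 1]) { out[q] <- pts[n, 2]; next }
    for (s in 1:(n - 1)) {
      if (v <= pts[s + 1, 1]) {
        t <- (v - pts[s, 1]) / (pts[s + 1, 1] - pts[s, 1])
        out[q] <- (1 - t) * pts[s, 2] + t * pts[s + 1, 2]
        break
      }
    }
  }
  out
}

# brute-force per-ray compositing of an axis-aligned orthographic render;
# independent of the package's vectorized path
oracle_render <- function(vol, azimuth, d, tf, early = 0.999) {
  dims <- dim(vol$data)
  ray_axis <- if (azimuth == 0) 3L else 2L
  extent <- (dims[ray_axis] - 1) * vol$spacing[ray_axis]
  depths <- c()
  t <- d / 2
  while (t < extent) { depths <- c(depths, t); t <- t + d }
  if (azimuth == 0) { nr <- dims[2]; nc <- dims[1] } else { nr <- dims[3]; nc <- dims[1] }
  I <- matrix(0, nr, nc); A <- matrix(0, nr, nc)
  expo <- d / tf$opacity_unit_distance
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc_i <- 0; acc_a <- 0
    for (t in depths) {
      p <- if (azimuth == 0) {
        c((cc - 1) * vol$spacing[1], (r - 1) * vol$spacing[2], t)
      } else {
        c((cc - 1) * vol$spacing[1], t, (r - 1) * vol$spacing[3])
      }
      v <- oracle_trilinear(vol$data, vol$spacing, p)
      a <- oracle_ramp(tf$opacity_points, v)
      g <- oracle_ramp(tf$gray_points, v)
      a <- 1 - (1 - a)^expo
      acc_i <- acc_i + (1 - acc_a) * a * g
      acc_a <- acc_a + (1 - acc_a) * a
      if (acc_a >= early) break
    }
    I[r, cc] <- acc_i; A[r, cc] <- acc_a
  }
  list(pixels = I, alpha = A)
}

# spreadsheet-definition STEYX: explicit two-pass OLS
oracle_steyx <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  sse <- sum((y - intercept - slope * x)^2)
  sqrt(sse / (n - 2))
}

# FWHM of (box of width w_box) convolved with (Gaussian sigma) by numerical
# convolution on a fine grid and linear interpolation of the half-max crossings
oracle_box_gauss_fwhm <- function(w_box = 1, sigma = 4, dz = 0.005, span = 30) {
  zk <- seq(-w_box / 2, w_box / 2, by = dz)      # box support samples
  z <- seq(-span, span, by = dz)                 # output grid
  prof <- colSums(exp(-outer(zk, z, function(a, b) (b - a)^2) / (2 * sigma^2)))
  half <- max(prof) / 2
  above <- which(prof >= half)
  i1 <- above[1]; i2 <- above[length(above)]
  cross <- function(ia, ib) {
    z[ia] + (half - prof[ia]) * (z[ib] - z[ia]) / (prof[ib] - prof[ia])
  }
  cross(i2, i2 + 1) - cross(i1, i1 - 1)
}

# small generic volume with reproducible pseudo-random content
make_test_volume <- function(dims = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1,
                             origin = c(0, 0, 0)) {
  set.seed(seed)
  tomo_volume(array(runif(prod(dims)), dims), spacing, origin)
}

# small phantom used by several suites: one 2 mm disk, fast to generate
small_phantom_spec <- function(seed = 5, noise_sigma = 0.01, z_spread_sigma = 2) {
  phantom_spec(volume_shape = c(96L, 48L, 40L), disk_diameters = 2.0,
               disk_center_z = 20, z_spread_sigma = z_spread_sigma,
               noise_sigma = noise_sigma, seed = seed)
}
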