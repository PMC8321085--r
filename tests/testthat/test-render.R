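test_that("the Nyquist bound doubles the smallest spacing", {
  expect_identical(nyquist_bound(0.085), 0.17)
  expect_identical(nyquist_bound(1.0), 2.0)
  expect_error(nyquist_bound(0), "domain")
  expect_error(nyquist_bound(-0.1), "domain")
})

test_that("the automatic sampling distance follows its power law", {
  expect_identical(auto_sampling_distance(1), 3580.5)
  # direct evaluation of 3580.5 * n^(-0.621) at 8e6 voxels
  expect_equal(auto_sampling_distance(8e6), 3580.5 * 8e6^(-0.621))
  expect_equal(auto_sampling_distance(8e6), 0.185, tolerance = 1e-3)
  expect_gt(auto_sampling_distance(1e6), auto_sampling_distance(1e7))
  expect_error(auto_sampling_distance(0), "domain")
})

test_that("composite_ray reproduces hand-evaluated recurrences", {
  expect_equal(composite_ray(cbind(0.7, 1), d = 0.3, unit_d = 1),
               c(intensity = 0.7, alpha = 1))
  expect_equal(composite_ray(NULL, d = 1, unit_d = 1),
               c(intensity = 0, alpha = 0))
  expect_equal(composite_ray(matrix(numeric(0), ncol = 2), d = 1, unit_d = 1),
               c(intensity = 0, alpha = 0))
  # two samples (g=1, a=0.5) at d = unit_d: I = 0.5 + 0.5*0.5 = 0.75
  expect_equal(composite_ray(cbind(c(1, 1), c(0.5, 0.5)), d = 1, unit_d = 1),
               c(intensity = 0.75, alpha = 0.75))
  expect_error(composite_ray(cbind(1.2, 0.5), d = 1, unit_d = 1), "domain")
  expect_error(composite_ray(cbind(0.5, -0.1), d = 1, unit_d = 1), "domain")
})

test_that("opacity correction makes homogeneous-ray alpha independent of d", {
  L <- 8; unit_d <- 1; a <- 0.3
  for (d in c(1, 0.5, 0.25, 0.125)) {
    n <- L / d
    res <- composite_ray(cbind(rep(0.8, n), rep(a, n)), d = d, unit_d = unit_d,
                         early_termination_alpha = 1)
    expect_equal(unname(res["alpha"]), 1 - (1 - a)^(L / unit_d), tolerance = 1e-6,
                 label = sprintf("d = %g", d))
  }
})

test_that("homogeneous volumes render to uniform images at both azimuths", {
  v <- tomo_volume(array(0.5, c(6, 7, 8)), c(1, 1, 1))
  tf <- transfer_function(c(0, 1))
  for (az in c(0, 90)) {
    img <- render(v, render_config(azimuth = az, sampling_distance = 0.4, tf = tf))
    expect_lt(max(img$pixels) - min(img$pixels), 1e-9)
    expect_lt(max(img$alpha) - min(img$alpha), 1e-9)
  }
  expect_error(render_config(azimuth = 45), "azimuth")
})

test_that("an opaque front slab reduces the 90-degree view to that slab's grays", {
  set.seed(8)
  dims <- c(5, 10, 6)
  data <- array(0, dims)
  wall <- matrix(runif(dims[1] * dims[3], 0.5, 1), dims[1], dims[3])
  for (j in 1:4) data[, j, ] <- wall          # thick slab so interpolation stays inside
  v <- tomo_volume(data, c(1, 1, 1))
  # alpha jumps to 1 above 0.25; gray is the identity ramp
  tf <- transfer_function(c(0, 1),
                          opacity_points = cbind(c(0, 0.25, 0.2500001, 1), c(0, 0, 1, 1)),
                          gray_points = cbind(c(0, 1), c(0, 1)),
                          opacity_unit_distance = 1)
  img <- render(v, render_config(azimuth = 90, sampling_distance = 1, tf = tf))
  expect_equal(img$pixels, t(wall), tolerance = 1e-9)
  expect_true(all(img$alpha > 0.999))
})

test_that("rendering agrees with the brute-force per-ray compositing oracle", {
  vol <- make_test_volume(c(16, 16, 16), spacing = c(1, 1, 1), seed = 12)
  tf <- default_transfer_function(vol)
  d <- min(vol$spacing) / 8
  for (az in c(0, 90)) {
    img <- render(vol, render_config(azimuth = az, sampling_distance = d, tf = tf))
    ref <- oracle_render(vol, az, d, tf)
    expect_lt(sqrt(mean((img$pixels - ref$pixels)^2)), 1e-3)
    expect_lt(sqrt(mean((img$alpha - ref$alpha)^2)), 1e-3)
    expect_true(all(img$alpha <= 1 + 1e-12))
    expect_true(all(img$alpha >= 0))
  }
})

test_that("images at d = 0.05 and 0.025 agree to within 1% RMS on a smooth phantom", {
  spec <- small_phantom_spec(noise_sigma = 0)
  vol <- generate_phantom(spec)
  iso <- resample_z(vol, 0.085, kernel_spec("windowed_sinc", window = "hamming"))
  tf <- default_transfer_function(vol, 10)
  i1 <- render(iso, render_config(azimuth = 90, sampling_distance = 0.05, tf = tf))
  i2 <- render(iso, render_config(azimuth = 90, sampling_distance = 0.025, tf = tf))
  rng <- max(i2$pixels) - min(i2$pixels)
  expect_lt(sqrt(mean((i1$pixels - i2$pixels)^2)) / rng, 0.01)
})

test_that("early termination stops accumulation without changing saturated rays", {
  v <- tomo_volume(array(1, c(4, 4, 50)), c(1, 1, 1))
  tf <- transfer_function(c(0, 1), opacity_points = cbind(c(0, 1), c(0.9, 0.9)))
  img <- render(v, render_config(azimuth = 0, sampling_distance = 1, tf = tf,
                                 early_termination_alpha = 0.99))
  expect_true(all(img$alpha >= 0.99 & img$alpha <= 1))
})
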