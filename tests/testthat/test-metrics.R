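make_xz_image <- function(pixels, spacing = c(0.1, 0.1), origin = c(0, 0)) {
  tomo_image(pixels, matrix(1, nrow(pixels), ncol(pixels)), c("x", "z"),
             spacing, origin)
}

test_that("profile extraction averages the requested column band", {
  img <- make_xz_image(matrix(0.42, 30, 20))
  prof <- extract_profile(img, disk_center_x = 1.0, band_halfwidth = 2)
  expect_true(all(prof$intensity == 0.42))
  expect_equal(diff(prof$z_mm), rep(0.1, 29))

  set.seed(9)
  px <- matrix(runif(30 * 20), 30, 20)
  img2 <- make_xz_image(px)
  p0 <- extract_profile(img2, disk_center_x = 0.5, band_halfwidth = 0)
  expect_identical(p0$intensity, px[, 6])          # single column, col = x/dx + 1

  # Gaussian stripe in z: band mean must reproduce the generator values
  z <- (0:29) * 0.1
  stripe <- exp(-(z - 1.5)^2 / (2 * 0.2^2))
  img3 <- make_xz_image(matrix(rep(stripe, 20), 30, 20))
  p3 <- extract_profile(img3, disk_center_x = 1.0, band_halfwidth = 3)
  expect_equal(p3$intensity, stripe, tolerance = 1e-9)

  expect_error(extract_profile(img, disk_center_x = 50), "outside")
  expect_error(extract_profile(img, disk_center_x = 0, band_halfwidth = 3), "band")
})

test_that("Gaussian-fit FWHM recovers closed-form widths and is affine-invariant", {
  z <- seq(0, 40, by = 0.25)
  g1 <- list(z_mm = z, intensity = exp(-(z - 20)^2 / 2))
  expect_equal(fit_fwhm(g1), 2 * sqrt(2 * log(2)), tolerance = 1e-6)

  g2 <- list(z_mm = z, intensity = 10 + 3 * exp(-(z - 17)^2 / (2 * 4)))
  expect_equal(fit_fwhm(g2), 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-6)

  # invariance under offset and scaling
  g3 <- list(z_mm = z, intensity = 100 + 2 * g2$intensity)
  expect_equal(fit_fwhm(g3), fit_fwhm(g2), tolerance = 1e-9)

  expect_error(fit_fwhm(list(z_mm = 1:4, intensity = c(1, 2, 1, 0))), "5")
  expect_error(fit_fwhm(list(z_mm = z, intensity = rep(1, length(z)))), "constant")
})

test_that("FWHM stays within 2% under 1% amplitude noise (seeded replicates)", {
  z <- seq(0, 60, by = 0.5)
  true_fwhm <- 2 * sqrt(2 * log(2)) * 3
  set.seed(14)
  errs <- replicate(100, {
    y <- exp(-(z - 30)^2 / (2 * 9)) + rnorm(length(z), sd = 0.01)
    fit_fwhm(list(z_mm = z, intensity = y)) - true_fwhm
  })
  expect_lt(max(abs(errs)) / true_fwhm, 0.02)
  expect_equal(true_fwhm, 7.0644, tolerance = 1e-4)
})

test_that("CNR reproduces its defining arithmetic on constructed ROIs", {
  # disk patch at 1.0; background patches with mean 0.5 and sample SD exactly
  # 0.1: 120 cells alternating 0.4/0.6 plus one odd cell at 0.5
  vals <- rep(c(0.4, 0.6), length.out = 120)
  bg <- matrix(c(vals, 0.5), 11, 11)
  img <- make_xz_image(matrix(0.5, 40, 60))
  img$pixels[10:20, 10:20] <- 1.0                   # disk
  img$pixels[10:20, 25:35] <- bg
  img$pixels[10:20, 40:50] <- bg
  got <- cnr(img,
             roi_spec(c(15, 15), c(5, 5), "disk"),
             roi_spec(c(15, 30), c(5, 5), "background"),
             roi_spec(c(15, 45), c(5, 5), "background"))
  expect_equal(got, 5.0)                            # (1.0 - 0.5) / 0.1

  # null contrast
  img$pixels[10:20, 10:20] <- bg
  expect_equal(cnr(img, roi_spec(c(15, 15), c(5, 5)),
                   roi_spec(c(15, 30), c(5, 5), "background"),
                   roi_spec(c(15, 45), c(5, 5), "background")),
               0, tolerance = 1e-12)
})

test_that("CNR is invariant under affine rescaling of the image", {
  set.seed(15)
  img <- make_xz_image(matrix(runif(40 * 60), 40, 60))
  img$pixels[10:20, 10:20] <- img$pixels[10:20, 10:20] + 0.5
  img$pixels <- pmin(img$pixels, 1)
  rois <- list(roi_spec(c(15, 15), c(5, 5)),
               roi_spec(c(15, 30), c(5, 5), "background"),
               roi_spec(c(15, 45), c(5, 5), "background"))
  v1 <- cnr(img, rois[[1]], rois[[2]], rois[[3]])
  img2 <- img
  img2$pixels <- 0.2 + 0.5 * img$pixels             # affine map, stays in [0,1]
  v2 <- cnr(img2, rois[[1]], rois[[2]], rois[[3]])
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("measured CNR tracks the known contrast-to-noise of generated images", {
  # disk raised by delta over background with i.i.d. noise SD tau:
  # the estimator must land within 3 standard errors of delta / tau
  delta <- 0.3; tau <- 0.05
  set.seed(17)
  vals <- replicate(50, {
    px <- matrix(0.4 + rnorm(40 * 60, sd = tau), 40, 60)
    px[10:20, 10:20] <- px[10:20, 10:20] + delta
    img <- make_xz_image(pmin(pmax(px, 0), 1))
    cnr(img, roi_spec(c(15, 15), c(5, 5)),
        roi_spec(c(15, 30), c(5, 5), "background"),
        roi_spec(c(15, 45), c(5, 5), "background"))
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - delta / tau), 3 * se)
})

test_that("CNR rejects degenerate and overlapping ROI geometry", {
  img <- make_xz_image(matrix(0.5, 40, 60))
  expect_error(cnr(img, roi_spec(c(15, 15), c(5, 5)),
                   roi_spec(c(15, 30), c(5, 5), "background"),
                   roi_spec(c(15, 45), c(5, 5), "background")),
               "zero variability")
  expect_error(cnr(img, roi_spec(c(15, 15), c(5, 5)),
                   roi_spec(c(15, 20), c(5, 5), "background"),
                   roi_spec(c(15, 45), c(5, 5), "background")),
               "disjoint")
  expect_error(cnr(img, roi_spec(c(2, 2), c(5, 5)),
                   roi_spec(c(15, 30), c(5, 5), "background"),
                   roi_spec(c(15, 45), c(5, 5), "background")),
               "bounds")
})

test_that("smoothness matches hand-computed OLS on the 3-point example", {
  prof <- list(z_mm = c(1, 2, 3), intensity = c(1, 2, 4))
  # hand OLS: slope 1.5, intercept -2/3, SSE 1/6, STEYX = sqrt(1/6)
  expect_equal(smoothness(prof, z_range = c(1, 3)), 1 / sqrt(1 / 6),
               tolerance = 1e-12)
  expect_equal(smoothness(prof, z_range = c(1, 3)), 2.4495, tolerance = 1e-4)

  # homogeneity: scaling intensities by c scales smoothness by 1/c
  prof2 <- list(z_mm = prof$z_mm, intensity = 10 * prof$intensity)
  expect_equal(smoothness(prof2, z_range = c(1, 3)),
               smoothness(prof, z_range = c(1, 3)) / 10, tolerance = 1e-12)
})

test_that("smoothness agrees with the spreadsheet STEYX oracle on random profiles", {
  set.seed(16)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    z <- sort(runif(n, 0, 40))
    y <- runif(n)
    prof <- list(z_mm = z, intensity = y)
    expect_equal(smoothness(prof, z_range = c(0, 40)),
                 1 / oracle_steyx(z, y), tolerance = 1e-12)
  }
})

test_that("smoothness signals collinearity and starved windows as structured errors", {
  lin <- list(z_mm = 1:10, intensity = 2 * (1:10) + 3)
  expect_error(smoothness(lin, z_range = c(1, 10)), "infinite")
  expect_identical(smoothness(lin, z_range = c(1, 10), on_collinear = "inf"), Inf)
  expect_error(smoothness(lin, z_range = c(1, 2)), "insufficient|>= 3")
})
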