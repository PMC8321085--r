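#' Extract a z line profile through a disk in a 90-degree image
#'
#' Averages a band of image columns centered on the disk's `x` position and
#' returns intensity as a function of world `z` (mm). Averaging a few columns
#' suppresses single-column noise without blurring the z direction under
#' study.
#'
#' @param img A [tomo_image] spanning `xz` (90-degree view).
#' @param disk_center_x World `x` (mm) of the disk center.
#' @param band_halfwidth Half-width of the column band in pixels; the band
#'   holds `2 * band_halfwidth + 1` columns (default 2).
#' @return A `line_profile`: list with `z_mm` (strictly increasing, uniform
#'   step) and `intensity`.
#' @export
extract_profile <- function(img, disk_center_x, band_halfwidth = 2L) {
  if (!inherits(img, "tomo_image") || !identical(img$axes, c("x", "z"))) {
    stop("dbtvr_usage_error: extract_profile needs a tomo_image spanning xz",
         call. = FALSE)
  }
  band_halfwidth <- as.integer(band_halfwidth)
  if (band_halfwidth < 0L) {
    stop("dbtvr_domain_error: band_halfwidth must be >= 0", call. = FALSE)
  }
  nc <- ncol(img$pixels)
  col0 <- round((disk_center_x - img$axis_origin[1]) / img$pixel_spacing[1]) + 1
  if (col0 < 1 || col0 > nc) {
    stop("dbtvr_geometry_error: disk_center_x lies outside the image", call. = FALSE)
  }
  cols <- (col0 - band_halfwidth):(col0 + band_halfwidth)
  if (cols[1] < 1 || cols[length(cols)] > nc) {
    stop("dbtvr_geometry_error: column band exceeds the image", call. = FALSE)
  }
  intensity <- rowMeans(img$pixels[, cols, drop = FALSE])
  z_mm <- img$axis_origin[2] + (seq_len(nrow(img$pixels)) - 1) * img$pixel_spacing[2]
  structure(list(z_mm = z_mm, intensity = as.double(intensity)),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d points, z in [%.3g, %.3g] mm\n",
              length(x$z_mm), min(x$z_mm), max(x$z_mm)))
  invisible(x)
}

#' Gaussian-fit full width at half maximum of a profile
#'
#' Least-squares fit of `y = b + A * exp(-(z - mu)^2 / (2 sigma^2))` with
#' `A > 0`, `sigma > 0`, returning `2 * sqrt(2 * log(2)) * sigma` (mm). The
#' FWHM of the 5 mm disk's z profile is the study's indicator of feature
#' definition at 90 degrees: disks are 1 mm thick, but out-of-plane smearing
#' makes the observed width much larger, and lower FWHM means better
#' definition. A constant background offset `b` is included in the model
#' since rendered profiles do not decay to zero.
#'
#' Initialization is moment-based (`mu` from the argmax, `sigma` from the
#' second moment of the above-half-range mass, `b` from the profile minimum);
#' the Levenberg-Marquardt fit is restarted from perturbed widths a bounded
#' number of times before giving up.
#'
#' @param profile A `line_profile` (or list with `z_mm`, `intensity`) of at
#'   least 5 points, non-constant.
#' @return FWHM in mm.
#' @examples
#' z <- seq(0, 40, by = 0.5)
#' fit_fwhm(list(z_mm = z, intensity = exp(-(z - 20)^2 / (2 * 4))))
#' @export
fit_fwhm <- function(profile) {
  z <- as.double(profile$z_mm)
  y <- as.double(profile$intensity)
  if (length(z) < 5L) {
    stop("dbtvr_usage_error: need at least 5 profile points", call. = FALSE)
  }
  if (max(y) - min(y) <= 0) {
    stop("dbtvr_fit_error: constant profile has no width", call. = FALSE)
  }
  b0 <- min(y)
  A0 <- max(y) - b0
  mu0 <- z[which.max(y)]
  w <- pmax(y - (b0 + A0 / 2), 0)
  sigma0 <- sqrt(sum(w * (z - mu0)^2) / sum(w))
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- diff(range(z)) / 10
  starts <- c(1, 0.5, 2, 0.25, 4)
  for (f in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + A * exp(-(z - mu)^2 / (2 * sigma^2)),
        start = list(b = b0, A = A0, mu = mu0, sigma = sigma0 * f),
        lower = c(b = -Inf, A = 1e-12, mu = min(z), sigma = 1e-9),
        upper = c(b = Inf, A = Inf, mu = max(z), sigma = diff(range(z)) * 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sigma <- stats::coef(fit)[["sigma"]]
      return(2 * sqrt(2 * log(2)) * sigma)
    }
  }
  stop(sprintf(paste0("dbtvr_fit_error: Gaussian fit failed after %d restarts ",
                      "(n = %d, range = [%.3g, %.3g], start sigma = %.3g)"),
               length(starts), length(z), min(y), max(y), sigma0), call. = FALSE)
}

#' Rectangular region of interest in a rendered image
#'
#' @param center Integer `(row, col)` pixel center.
#' @param half_extent Integer `(dr, dc)`; the ROI spans
#'   `2 * half_extent + 1` pixels per axis.
#' @param role `"disk"` or `"background"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, half_extent = c(5L, 5L),
                     role = c("disk", "background")) {
  role <- match.arg(role)
  structure(list(center = as.integer(center), half_extent = as.integer(half_extent),
                 role = role), class = "roi_spec")
}

roi_values <- function(img, roi) {
  r <- roi$center[1] + (-roi$half_extent[1]):(roi$half_extent[1])
  c <- roi$center[2] + (-roi$half_extent[2]):(roi$half_extent[2])
  if (min(r) < 1 || max(r) > nrow(img$pixels) || min(c) < 1 || max(c) > ncol(img$pixels)) {
    stop("dbtvr_geometry_error: ROI exceeds image bounds", call. = FALSE)
  }
  img$pixels[r, c]
}

roi_overlap <- function(a, b) {
  all(abs(a$center - b$center) <= a$half_extent + b$half_extent)
}

#' Contrast-to-noise ratio of a disk against two background regions
#'
#' `CNR = (mu_disk - mu_BG) / sigma_BG`, where `mu_BG` is the mean of the two
#' background ROI means and `sigma_BG` the mean of their sample standard
#' deviations (n - 1 denominator, matching the spreadsheet-function family
#' used for this class of phantom analysis).
#'
#' @param img A [tomo_image].
#' @param disk,bg1,bg2 [roi_spec]s; must lie inside the image and not overlap.
#' @param detail If `TRUE`, also return the component means/SDs.
#' @return The CNR (dimensionless), or a list when `detail = TRUE`.
#' @export
cnr <- function(img, disk, bg1, bg2, detail = FALSE) {
  if (!inherits(img, "tomo_image")) {
    stop("dbtvr_usage_error: expected a `tomo_image`", call. = FALSE)
  }
  if (roi_overlap(disk, bg1) || roi_overlap(disk, bg2) || roi_overlap(bg1, bg2)) {
    stop("dbtvr_usage_error: ROIs must be disjoint", call. = FALSE)
  }
  vd <- roi_values(img, disk)
  v1 <- roi_values(img, bg1)
  v2 <- roi_values(img, bg2)
  mu_disk <- mean(vd)
  mu_bg <- mean(c(mean(v1), mean(v2)))
  sigma_bg <- mean(c(stats::sd(as.vector(v1)), stats::sd(as.vector(v2))))
  if (!is.finite(sigma_bg) || sigma_bg == 0) {
    stop("dbtvr_undefined_cnr_error: background ROIs have zero variability",
         call. = FALSE)
  }
  value <- (mu_disk - mu_bg) / sigma_bg
  if (detail) {
    list(cnr = value, mu_disk = mu_disk, mu_bg = mu_bg, sigma_bg = sigma_bg)
  } else {
    value
  }
}

#' Profile smoothness as reciprocal regression standard error
#'
#' Restricts the profile to `z_range`, fits the ordinary least-squares line
#' of intensity on z, and returns `1 / STEYX` where
#' `STEYX = sqrt(SSE / (n - 2))` is the standard error of the predicted y
#' (the spreadsheet STEYX definition). The window defaults to (16, 24) mm, a
#' region of high intensity variation on the disk profile; a smoother profile
#' leaves smaller residuals around the local trend line, hence a larger
#' score. Inverse intensity units: scaling the profile by `c` scales
#' smoothness by `1/c`.
#'
#' @param profile A `line_profile`.
#' @param z_range Numeric `(lo, hi)` window in mm, inclusive; default
#'   `c(16, 24)`.
#' @param on_collinear What to do when the residuals are exactly zero:
#'   `"error"` (default) signals a `dbtvr_infinite_smoothness_error`;
#'   `"inf"` returns `Inf`.
#' @return The smoothness score (reciprocal intensity units).
#' @examples
#' smoothness(list(z_mm = c(1, 2, 3), intensity = c(1, 2, 4)), z_range = c(1, 3))
#' @export
smoothness <- function(profile, z_range = c(16, 24),
                       on_collinear = c("error", "inf")) {
  on_collinear <- match.arg(on_collinear)
  keep <- profile$z_mm >= z_range[1] & profile$z_mm <= z_range[2]
  z <- as.double(profile$z_mm[keep])
  y <- as.double(profile$intensity[keep])
  n <- length(z)
  if (n < 3L) {
    stop("dbtvr_insufficient_data_error: need >= 3 profile points inside z_range",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ z)
  sse <- sum(stats::residuals(fit)^2)
  steyx <- sqrt(sse / (n - 2))
  if (steyx <= .Machine$double.eps * max(abs(y), 1)) {
    if (on_collinear == "inf") return(Inf)
    stop("dbtvr_infinite_smoothness_error: residuals are zero (collinear points)",
         call. = FALSE)
  }
  1 / steyx
}
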