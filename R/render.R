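#' Transfer function mapping scalar values to opacity and gray level
#'
#' Piecewise-linear opacity and gray ramps over a scalar range, plus the
#' opacity unit distance: the path length (mm) at which a sample's nominal
#' opacity applies. During compositing at sampling distance `d`, per-sample
#' opacity is corrected to `1 - (1 - alpha)^(d / unit_distance)`, which keeps
#' the accumulated opacity of a homogeneous ray independent of `d`.
#'
#' The default is the simplest monotone choice: linear opacity 0 -> 1 and
#' linear gray 0 -> 1 over `scalar_range`, unit distance 1 mm. Values outside
#' the ramp are clamped to the end points.
#'
#' @param scalar_range Numeric `(lo, hi)`, `hi > lo`.
#' @param opacity_points,gray_points Two-column matrices `(scalar, value)`
#'   with non-decreasing scalar and values in `[0, 1]`; default a linear
#'   ramp over `scalar_range`.
#' @param opacity_unit_distance Unit distance in mm, `> 0`.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(scalar_range,
                              opacity_points = NULL,
                              gray_points = NULL,
                              opacity_unit_distance = 1.0) {
  scalar_range <- as.double(scalar_range)
  if (length(scalar_range) != 2L || !all(is.finite(scalar_range)) ||
      scalar_range[2] <= scalar_range[1]) {
    stop("dbtvr_domain_error: scalar_range must be (lo, hi) with hi > lo", call. = FALSE)
  }
  if (opacity_unit_distance <= 0) {
    stop("dbtvr_domain_error: opacity_unit_distance must be > 0", call. = FALSE)
  }
  ramp <- cbind(scalar_range, c(0, 1))
  opacity_points <- check_ramp(opacity_points %||% ramp, "opacity")
  gray_points <- check_ramp(gray_points %||% ramp, "gray")
  structure(list(scalar_range = scalar_range,
                 opacity_points = opacity_points,
                 gray_points = gray_points,
                 opacity_unit_distance = as.double(opacity_unit_distance)),
            class = "transfer_function")
}

check_ramp <- function(pts, what) {
  pts <- matrix(as.double(pts), ncol = 2)
  if (nrow(pts) < 2L || is.unsorted(pts[, 1])) {
    stop(sprintf("dbtvr_domain_error: %s ramp needs >= 2 points with non-decreasing scalar",
                 what), call. = FALSE)
  }
  if (any(pts[, 2] < 0) || any(pts[, 2] > 1)) {
    stop(sprintf("dbtvr_domain_error: %s ramp values must lie in [0, 1]", what),
         call. = FALSE)
  }
  pts
}

#' Default transfer function for a volume
#'
#' Linear opacity and gray ramps over the volume's full `[min, max]` range.
#' All quantitative metrics depend on the transfer function, so studies
#' should hold it fixed across the configurations they compare.
#'
#' @param vol A [tomo_volume].
#' @param opacity_unit_distance Unit distance in mm (default 1).
#' @return A [transfer_function].
#' @export
default_transfer_function <- function(vol, opacity_unit_distance = 1.0) {
  stopifnot_volume(vol)
  rng <- range(vol$data)
  if (rng[2] <= rng[1]) rng <- rng + c(0, 1)   # constant volume: degenerate ramp
  transfer_function(rng, opacity_unit_distance = opacity_unit_distance)
}

tf_eval <- function(tf, values) {
  a <- stats::approx(tf$opacity_points[, 1], tf$opacity_points[, 2], xout = values,
                     rule = 2, ties = "ordered")$y
  g <- stats::approx(tf$gray_points[, 1], tf$gray_points[, 2], xout = values,
                     rule = 2, ties = "ordered")$y
  list(alpha = a, gray = g)
}

#' Rendering configuration
#'
#' @param azimuth Camera azimuth in degrees: `0` (rays along `+z`, image
#'   spans `xy`, the view parallel to the detector) or `90` (rays along `+y`,
#'   image spans `xz`, the view perpendicular to the detector where z-quality
#'   is visible).
#' @param sampling_distance Distance `d` (mm) between consecutive samples
#'   along each ray, `> 0`. The study grid used by the sweep module is
#'   [default_sampling_distances()].
#' @param tf A [transfer_function], or `NULL` to use
#'   [default_transfer_function()] of the rendered volume.
#' @param early_termination_alpha Accumulated-opacity threshold in `(0, 1]`
#'   beyond which a ray stops accumulating (default 0.999).
#' @return An object of class `render_config`.
#' @export
render_config <- function(azimuth = 90, sampling_distance = 1.0, tf = NULL,
                          early_termination_alpha = 0.999) {
  if (!azimuth %in% c(0, 90)) {
    stop("dbtvr_usage_error: azimuth must be 0 or 90 degrees", call. = FALSE)
  }
  if (length(sampling_distance) != 1L || is.na(sampling_distance) ||
      sampling_distance <= 0) {
    stop("dbtvr_domain_error: sampling_distance must be > 0", call. = FALSE)
  }
  if (early_termination_alpha <= 0 || early_termination_alpha > 1) {
    stop("dbtvr_domain_error: early_termination_alpha must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(tf) && !inherits(tf, "transfer_function")) {
    stop("dbtvr_usage_error: tf must be a transfer_function or NULL", call. = FALSE)
  }
  structure(list(azimuth = azimuth, sampling_distance = as.double(sampling_distance),
                 tf = tf, early_termination_alpha = as.double(early_termination_alpha)),
            class = "render_config")
}

#' Nyquist bound on the ray-casting sampling distance
#'
#' The sampling theorem applied to ray marching: the distance between two
#' consecutive accumulations must not exceed twice the smallest voxel
#' spacing. For the 0.085 mm in-plane spacing of DBT reconstructions this is
#' 0.170 mm.
#'
#' @param min_spacing Smallest voxel spacing in mm, `> 0`.
#' @return The bound `2 * min_spacing` in mm.
#' @examples
#' nyquist_bound(0.085)
#' @export
nyquist_bound <- function(min_spacing) {
  if (any(!is.finite(min_spacing)) || any(min_spacing <= 0)) {
    stop("dbtvr_domain_error: min_spacing must be > 0", call. = FALSE)
  }
  2 * min_spacing
}

#' Empirical automatic sampling distance
#'
#' The power-law `3580.5 * n^(-0.621)` relating a data set's voxel count to
#' the sampling distance chosen by the automatic mode of a standard
#' volume-rendering toolkit, fitted on DBT data. For the ~8 million voxels of
#' a native DBT reconstruction it yields about 0.185 mm; the value 0.195 mm
#' appears in the study grid as "automatic sampling distance".
#'
#' @param n_voxels Total voxel count, `>= 1`.
#' @return Sampling distance in mm.
#' @examples
#' auto_sampling_distance(8e6)
#' @export
auto_sampling_distance <- function(n_voxels) {
  if (any(!is.finite(n_voxels)) || any(n_voxels < 1)) {
    stop("dbtvr_domain_error: n_voxels must be >= 1", call. = FALSE)
  }
  3580.5 * n_voxels^(-0.621)
}

#' Composite one ray front-to-back
#'
#' Reference implementation of the compositing recurrence for a single ray.
#' Each sample's nominal opacity is first corrected for the sampling
#' distance, `alpha' = 1 - (1 - alpha)^(d / unit_d)`; then, front to back,
#' `I += (1 - A) * alpha' * g` and `A += (1 - A) * alpha'`, stopping early
#' once `A >= early_termination_alpha`. An empty sample list yields
#' `(0, 0)` (background).
#'
#' @param samples Two-column matrix `(gray, alpha)` ordered front to back,
#'   values in `[0, 1]`.
#' @param d Sampling distance in mm.
#' @param unit_d Opacity unit distance in mm.
#' @param early_termination_alpha Stop threshold (default 0.999).
#' @return Named numeric `c(intensity, alpha)`.
#' @examples
#' composite_ray(cbind(c(1, 1), c(0.5, 0.5)), d = 1, unit_d = 1)
#' @export
composite_ray <- function(samples, d, unit_d, early_termination_alpha = 0.999) {
  if (is.null(samples) || length(samples) == 0L) {
    return(c(intensity = 0, alpha = 0))
  }
  samples <- matrix(as.double(samples), ncol = 2)
  if (any(samples < 0) || any(samples > 1)) {
    stop("dbtvr_domain_error: sample gray/alpha values must lie in [0, 1]",
         call. = FALSE)
  }
  expo <- d / unit_d
  I <- 0; A <- 0
  for (s in seq_len(nrow(samples))) {
    a_corr <- 1 - (1 - samples[s, 2])^expo
    I <- I + (1 - A) * a_corr * samples[s, 1]
    A <- A + (1 - A) * a_corr
    if (A >= early_termination_alpha) break
  }
  c(intensity = I, alpha = A)
}

#' Orthographic composite volume rendering at 0 or 90 degrees
#'
#' Casts one orthographic ray per output pixel through the volume: at azimuth
#' 0 the rays run along `+z` and the image spans `xy`; at azimuth 90 they run
#' along `+y` and the image spans `xz`. Rays start half a sampling distance
#' inside the entry face and advance every `d` mm until the exit face
#' (half-open `[0, extent)` in the center-to-center span of the volume).
#' Scalars are sampled by trilinear interpolation; because the rays pass
#' exactly through the in-plane voxel centers, trilinear interpolation
#' reduces to 1-D linear interpolation along the ray axis, which is how it is
#' computed. Samples are mapped through the transfer function and composited
#' front-to-back with opacity-corrected alpha (see [composite_ray()]); rays
#' whose accumulated opacity reaches the early-termination threshold stop
#' accumulating. Pixel spacing equals the voxel spacing of the spanned axes.
#'
#' @param vol A [tomo_volume].
#' @param cfg A [render_config].
#' @return A [tomo_image].
#' @examples
#' v <- tomo_volume(array(runif(16^3), c(16, 16, 16)), c(1, 1, 1))
#' img <- render(v, render_config(azimuth = 0, sampling_distance = 0.5))
#' @export
render <- function(vol, cfg) {
  stopifnot_volume(vol)
  if (!inherits(cfg, "render_config")) {
    stop("dbtvr_usage_error: expected a `render_config`", call. = FALSE)
  }
  tf <- cfg$tf %||% default_transfer_function(vol)
  d <- cfg$sampling_distance
  expo <- d / tf$opacity_unit_distance
  dims <- dim(vol$data)
  ray_axis <- if (cfg$azimuth == 0) 3L else 2L
  n_axis <- dims[ray_axis]
  s_axis <- vol$spacing[ray_axis]
  extent <- (n_axis - 1) * s_axis
  # sample depths (mm from entry face), first at d/2, strictly inside [0, extent)
  depths <- if (extent <= d / 2) numeric(0) else {
    dd <- seq(d / 2, by = d, length.out = floor((extent - d / 2) / d) + 1L)
    dd[dd < extent]
  }

  if (cfg$azimuth == 0) {
    nr <- dims[2]; nc <- dims[1]
    axes <- c("x", "y")
    sp <- vol$spacing[1:2]; org <- vol$origin[1:2]
  } else {
    nr <- dims[3]; nc <- dims[1]
    axes <- c("x", "z")
    sp <- c(vol$spacing[1], vol$spacing[3]); org <- c(vol$origin[1], vol$origin[3])
  }
  npix <- nr * nc
  I <- numeric(npix)
  A <- numeric(npix)
  active <- rep(TRUE, npix)

  # flatten so that, at a fixed depth along the ray axis, the slab of values
  # across all rays is a contiguous gather; rows of the image are the second
  # spanned axis, columns x
  get_slab <- if (cfg$azimuth == 0) {
    function(k) as.vector(t(vol$data[, , k]))        # ny x nx, rows = y
  } else {
    function(j) as.vector(t(vol$data[, j, ]))        # nz x nx, rows = z
  }

  for (depth in depths) {
    p <- depth / s_axis
    k0 <- floor(p)
    fr <- p - k0
    k0 <- as.integer(k0) + 1L                        # 1-based
    k1 <- min(k0 + 1L, n_axis)
    slab <- if (fr == 0) get_slab(k0) else (1 - fr) * get_slab(k0) + fr * get_slab(k1)
    idx <- which(active)
    if (length(idx) == 0L) break
    m <- tf_eval(tf, slab[idx])
    a_corr <- 1 - (1 - m$alpha)^expo
    trans <- 1 - A[idx]
    I[idx] <- I[idx] + trans * a_corr * m$gray
    A[idx] <- A[idx] + trans * a_corr
    active[idx] <- A[idx] < cfg$early_termination_alpha
  }
  tomo_image(pixels = matrix(I, nr, nc), alpha = matrix(A, nr, nc),
             axes = axes, pixel_spacing = sp, axis_origin = org)
}
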