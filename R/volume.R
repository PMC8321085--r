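#' 3D scalar volume with anisotropic voxel spacing
#'
#' A `tomo_volume` is the package's container for reconstructed tomosynthesis
#' data: a 3D numeric array indexed `(i, j, k)` along the world axes
#' `(x, y, z)`, together with per-axis voxel spacing in mm and a world origin.
#' The world coordinate of voxel `(i, j, k)` (0-based) is
#' `origin + (i * sx, j * sy, k * sz)`; `z` is the between-slice axis, the
#' coarse direction of DBT reconstructions (typically 0.085 x 0.085 x 1.0 mm).
#'
#' @param data 3D numeric array, finite values only.
#' @param spacing Numeric length-3, voxel spacing in mm, all strictly positive.
#' @param origin Numeric length-3, world position (mm) of voxel `(0, 0, 0)`.
#'   Default `c(0, 0, 0)`.
#' @return An object of class `tomo_volume`: a list with elements `data`,
#'   `spacing`, `origin`.
#' @examples
#' v <- tomo_volume(array(0, c(4, 4, 4)), spacing = c(0.085, 0.085, 1))
#' dim(v$data)
#' @export
tomo_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("dbtvr_dimensionality_error: `data` must be a 3D array", call. = FALSE)
  }
  storage.mode(data) <- "double"
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("dbtvr_format_error: `spacing` must be 3 strictly positive values (mm)",
         call. = FALSE)
  }
  if (length(origin) != 3L || anyNA(origin)) {
    stop("dbtvr_format_error: `origin` must be 3 finite values (mm)", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("dbtvr_format_error: volume data must be finite (no NaN/Inf)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "tomo_volume")
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

stopifnot_volume <- function(vol) {
  if (!inherits(vol, "tomo_volume")) {
    stop("dbtvr_usage_error: expected a `tomo_volume`", call. = FALSE)
  }
  invisible(vol)
}

# world extent (mm) spanned by voxel centers along each axis
volume_extent <- function(vol) {
  (dim(vol$data) - 1L) * vol$spacing
}

#' Rendered 2D image produced by the ray caster
#'
#' Holds the composited intensity and accumulated opacity of an orthographic
#' rendering, plus enough geometry to map pixels back to world mm. Rows run
#' along the second spanned world axis (`y` for a 0-degree view, `z` for a
#' 90-degree view) and columns along `x`, so a 90-degree image is a
#' conventional xz view with depth down the rows.
#'
#' @param pixels Numeric matrix of composited intensities in `[0, 1]`;
#'   rows = second spanned axis, cols = x.
#' @param alpha Numeric matrix of accumulated opacities in `[0, 1]`, same
#'   shape as `pixels`.
#' @param axes Character length-2, the world axes spanned, `c("x","y")` or
#'   `c("x","z")`.
#' @param pixel_spacing Numeric length-2 `(col, row)` spacing in mm.
#' @param axis_origin Numeric length-2 `(col, row)` world mm of pixel `[1, 1]`.
#' @return An object of class `tomo_image`.
#' @export
tomo_image <- function(pixels, alpha, axes, pixel_spacing, axis_origin = c(0, 0)) {
  if (!is.matrix(pixels) || !is.matrix(alpha) || !all(dim(pixels) == dim(alpha))) {
    stop("dbtvr_format_error: `pixels` and `alpha` must be matrices of identical shape",
         call. = FALSE)
  }
  if (any(pixels < -1e-12) || any(pixels > 1 + 1e-12) ||
      any(alpha < -1e-12) || any(alpha > 1 + 1e-12)) {
    stop("dbtvr_format_error: pixel and alpha values must lie in [0, 1]", call. = FALSE)
  }
  pixels <- pmin(pmax(pixels, 0), 1)
  alpha <- pmin(pmax(alpha, 0), 1)
  axes <- as.character(axes)
  if (!identical(axes, c("x", "y")) && !identical(axes, c("x", "z"))) {
    stop("dbtvr_usage_error: `axes` must be c('x','y') or c('x','z')", call. = FALSE)
  }
  structure(list(pixels = pixels, alpha = alpha, axes = axes,
                 pixel_spacing = as.double(pixel_spacing),
                 axis_origin = as.double(axis_origin)),
            class = "tomo_image")
}

#' @export
print.tomo_image <- function(x, ...) {
  cat(sprintf("<tomo_image> %d x %d px spanning (%s, %s), spacing (%.4g, %.4g) mm\n",
              nrow(x$pixels), ncol(x$pixels), x$axes[1], x$axes[2],
              x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

#' Cross-sectional slice view of a volume
#'
#' Extracts one axis-aligned plane of a volume as a [tomo_image] after
#' linearly rescaling intensities to `[0, 1]` over the full volume range.
#' This is the package's radiometrically *linear* view: unlike a composited
#' rendering it preserves proportionality with the voxel values, which makes
#' it the right surface for checking generator properties (e.g. that a
#' z-profile through a disk equals the disk's box profile convolved with the
#' z-spread Gaussian).
#'
#' @param vol A [tomo_volume].
#' @param plane `"xz"` (fix a y index) or `"xy"` (fix a z index).
#' @param index 1-based index of the fixed axis; default the middle.
#' @return A [tomo_image] whose alpha channel is identically 1.
#' @export
slice_image <- function(vol, plane = c("xz", "xy"), index = NULL) {
  stopifnot_volume(vol)
  plane <- match.arg(plane)
  d <- dim(vol$data)
  rng <- range(vol$data)
  scale <- if (rng[2] > rng[1]) 1 / (rng[2] - rng[1]) else 1
  if (plane == "xz") {
    if (is.null(index)) index <- as.integer(ceiling(d[2] / 2))
    if (index < 1 || index > d[2]) stop("dbtvr_geometry_error: slice index out of bounds",
                                        call. = FALSE)
    sl <- (vol$data[, index, ] - rng[1]) * scale    # nx x nz
    tomo_image(pixels = t(sl), alpha = matrix(1, d[3], d[1]),
               axes = c("x", "z"),
               pixel_spacing = c(vol$spacing[1], vol$spacing[3]),
               axis_origin = c(vol$origin[1], vol$origin[3]))
  } else {
    if (is.null(index)) index <- as.integer(ceiling(d[3] / 2))
    if (index < 1 || index > d[3]) stop("dbtvr_geometry_error: slice index out of bounds",
                                        call. = FALSE)
    sl <- (vol$data[, , index] - rng[1]) * scale    # nx x ny
    tomo_image(pixels = t(sl), alpha = matrix(1, d[2], d[1]),
               axes = c("x", "y"),
               pixel_spacing = c(vol$spacing[1], vol$spacing[2]),
               axis_origin = c(vol$origin[1], vol$origin[2]))
  }
}
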