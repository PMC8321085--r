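#' Resample a volume along z to a new slice spacing
#'
#' Converts the anisotropic DBT grid to (near-)isotropic by interpolating
#' along `z` only, e.g. 0.085 x 0.085 x 1.0 mm -> 0.085 x 0.085 x 0.085 mm.
#' The in-plane grid is untouched. The output grid is anchored at the first
#' source slice (origin preserved) and contains
#' `floor((nz - 1) * sz / new_sz) + 1` slices, so it spans the source voxel
#' centers without extrapolation. Each output slice is a weighted sum of
#' source slices with taps from [build_taps()]; out-of-range source indices
#' are clamped to the edge slices, which avoids inventing data beyond the
#' breast support.
#'
#' @param vol A [tomo_volume].
#' @param new_sz New slice spacing in mm, `> 0`.
#' @param spec A [kernel_spec]; default Hamming windowed sinc with `W = 3`,
#'   `B = 1`.
#' @return A [tomo_volume] with spacing `(sx, sy, new_sz)`.
#' @examples
#' v <- tomo_volume(array(rnorm(4 * 4 * 10), c(4, 4, 10)), c(0.085, 0.085, 1))
#' iso <- resample_z(v, 0.5, kernel_spec("linear"))
#' dim(iso$data)
#' @export
resample_z <- function(vol, new_sz,
                       spec = kernel_spec("windowed_sinc", window = "hamming")) {
  stopifnot_volume(vol)
  if (length(new_sz) != 1L || is.na(new_sz) || new_sz <= 0) {
    stop("dbtvr_domain_error: new_sz must be > 0", call. = FALSE)
  }
  if (!inherits(spec, "kernel_spec")) {
    stop("dbtvr_usage_error: expected a `kernel_spec`", call. = FALSE)
  }
  d <- dim(vol$data)
  nz <- d[3]
  sz <- vol$spacing[3]
  nz2 <- floor((nz - 1) * sz / new_sz) + 1
  mat <- matrix(vol$data, nrow = d[1] * d[2], ncol = nz)
  out <- matrix(0, nrow = d[1] * d[2], ncol = nz2)
  for (k2 in seq_len(nz2)) {
    p <- (k2 - 1) * new_sz / sz              # position in source slice index space
    i0 <- floor(p + 1e-9)                    # guard: p may sit epsilon under an integer
    frac <- p - i0
    if (frac < 0) frac <- 0
    taps <- build_taps(spec, frac)
    src <- pmin(pmax(i0 + taps$offsets, 0), nz - 1) + 1L   # clamp to edges, 1-based
    acc <- mat[, src[1], drop = TRUE] * taps$weights[1]
    if (length(src) > 1L) {
      for (t in 2:length(src)) acc <- acc + mat[, src[t], drop = TRUE] * taps$weights[t]
    }
    out[, k2] <- acc
  }
  tomo_volume(array(out, dim = c(d[1], d[2], nz2)),
              spacing = c(vol$spacing[1], vol$spacing[2], new_sz),
              origin = vol$origin)
}
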