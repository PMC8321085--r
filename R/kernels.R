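#' Interpolation kernel specification
#'
#' Describes one member of the kernel family used for z-resampling: the plain
#' interpolators (`nearest`, `linear`, Catmull-Rom `cubic`) or a windowed-sinc
#' kernel, i.e. the ideal `sinc` reconstruction truncated by one of seven
#' standard window functions. Two parameters shape the windowed-sinc family:
#'
#' * **window half-width** `W` (in source samples, integer 1..16): half the
#'   kernel support; wider windows approximate ideal sinc reconstruction more
#'   closely at higher cost.
#' * **z blur factor** `B` (`>= 1`): scales the kernel argument (`x -> x/B`)
#'   and widens the support to `W * B`, low-pass filtering while
#'   interpolating; `B = 1` leaves the kernel interpolating.
#'
#' The Kaiser window takes a shape parameter `kaiser_alpha` (default 3,
#' matching the usual "adjustment off" setting of rendering toolkits).
#'
#' @param family One of `"nearest"`, `"linear"`, `"cubic"`, `"windowed_sinc"`.
#' @param window Window function for `windowed_sinc`: one of `"lanczos"`,
#'   `"kaiser"`, `"cosine"`, `"hann"`, `"hamming"`, `"blackman"`, `"nuttall"`.
#' @param W Window half-width in samples, integer in `[1, 16]`.
#' @param B Blur factor along the resampled axis, `>= 1`.
#' @param kaiser_alpha Kaiser shape parameter, `> 0`.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("windowed_sinc", window = "hamming", W = 5, B = 2)
#' @export
kernel_spec <- function(family = c("windowed_sinc", "nearest", "linear", "cubic"),
                        window = c("lanczos", "kaiser", "cosine", "hann",
                                   "hamming", "blackman", "nuttall"),
                        W = 3L, B = 1.0, kaiser_alpha = 3.0) {
  family <- match.arg(family)
  window <- if (family == "windowed_sinc") match.arg(window) else NA_character_
  W <- as.integer(W)
  if (family == "windowed_sinc") {
    if (is.na(W) || W < 1L || W > 16L) {
      stop("dbtvr_domain_error: W must be an integer in [1, 16]", call. = FALSE)
    }
  }
  if (is.na(B) || B < 1) {
    stop("dbtvr_domain_error: blur factor B must be >= 1", call. = FALSE)
  }
  if (family == "windowed_sinc" && window == "kaiser" &&
      (is.na(kaiser_alpha) || kaiser_alpha <= 0)) {
    stop("dbtvr_domain_error: kaiser_alpha must be > 0", call. = FALSE)
  }
  structure(list(family = family, window = window, W = W, B = as.double(B),
                 kaiser_alpha = as.double(kaiser_alpha)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s\n", kernel_id(x)))
  invisible(x)
}

#' Short identifier string for a kernel spec
#' @param spec A [kernel_spec].
#' @return A string such as `"hamming_W5_B2"` or `"cubic"`.
#' @export
kernel_id <- function(spec) {
  if (spec$family != "windowed_sinc") return(spec$family)
  sprintf("%s_W%d_B%g", spec$window, spec$W, spec$B)
}

# normalized sinc with sinc(0) = 1
sinc <- function(t) {
  out <- rep(1, length(t))
  nz <- t != 0
  out[nz] <- sin(pi * t[nz]) / (pi * t[nz])
  out
}

# window functions evaluated at u = t / W in [-1, 1]; zero outside
window_value <- function(window, u, kaiser_alpha) {
  w <- switch(window,
    lanczos  = sinc(u),
    cosine   = cos(pi * u / 2),
    hann     = 0.5 + 0.5 * cos(pi * u),
    hamming  = 0.54 + 0.46 * cos(pi * u),
    blackman = 0.42 + 0.5 * cos(pi * u) + 0.08 * cos(2 * pi * u),
    nuttall  = 0.355768 + 0.487396 * cos(pi * u) + 0.144232 * cos(2 * pi * u) +
               0.012604 * cos(3 * pi * u),
    kaiser   = besselI(kaiser_alpha * sqrt(pmax(0, 1 - u^2)), 0) /
               besselI(kaiser_alpha, 0),
    stop(sprintf("dbtvr_usage_error: unknown window '%s'", window), call. = FALSE))
  w * (abs(u) <= 1)
}

#' Evaluate an interpolation kernel at signed sample offsets
#'
#' Total function on the reals. For `windowed_sinc` the value is
#' `sinc(x/B) * window((x/B)/W)` for `|x/B| <= W`, else 0, with
#' `sinc(t) = sin(pi t)/(pi t)` and `sinc(0) = 1`. `linear` is the hat
#' function `max(0, 1 - |x|)`; `nearest` is 1 on `[-0.5, 0.5)` (ties resolve
#' toward the lower source index) and 0 elsewhere; `cubic` is the Catmull-Rom
#' kernel.
#'
#' @param spec A [kernel_spec].
#' @param x Numeric vector of signed offsets in source samples.
#' @return Numeric vector of raw (unnormalized) kernel weights.
#' @examples
#' kernel_weight(kernel_spec("linear"), c(-0.5, 0, 0.25))
#' @export
kernel_weight <- function(spec, x) {
  if (!inherits(spec, "kernel_spec")) {
    stop("dbtvr_usage_error: expected a `kernel_spec`", call. = FALSE)
  }
  x <- as.double(x)
  switch(spec$family,
    nearest = as.double(x >= -0.5 & x < 0.5),
    linear = pmax(0, 1 - abs(x)),
    cubic = catmull_rom(x),
    windowed_sinc = {
      t <- x / spec$B
      sinc(t) * window_value(spec$window, t / spec$W, spec$kaiser_alpha)
    })
}

# Catmull-Rom cubic (a = -1/2)
catmull_rom <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

# kernel support in source samples on each side of the interpolation point
kernel_support <- function(spec) {
  switch(spec$family,
    nearest = 1L,
    linear = 1L,
    cubic = 2L,
    windowed_sinc = as.integer(ceiling(spec$W * spec$B)))
}

#' Discrete interpolation taps for one fractional position
#'
#' Builds the finite set of source-sample offsets and weights used to
#' interpolate at position `i + frac` between source samples. Offsets span
#' the full kernel support around `frac`; raw weights come from
#' [kernel_weight()] evaluated at `offset - frac` and are renormalized to sum
#' exactly 1, which pins the DC gain of the resampler at 1 regardless of
#' truncation. Zero-weight taps are dropped.
#'
#' @param spec A [kernel_spec].
#' @param frac Fractional position in `[0, 1)`.
#' @return A list with `offsets` (integer) and `weights` (numeric, unit sum),
#'   of class `tap_set`.
#' @examples
#' build_taps(kernel_spec("linear"), 0.5)
#' @export
build_taps <- function(spec, frac) {
  if (length(frac) != 1L || is.na(frac) || frac < 0 || frac >= 1) {
    stop("dbtvr_domain_error: frac must lie in [0, 1)", call. = FALSE)
  }
  S <- kernel_support(spec)
  offsets <- seq.int(-S + 1L, S)
  w <- kernel_weight(spec, offsets - frac)
  # drop exact zeros and fp residue of sinc zeros at integer arguments
  keep <- abs(w) > 1e-14 * max(abs(w))
  offsets <- offsets[keep]
  w <- w[keep]
  total <- sum(w)
  if (!is.finite(total) || abs(total) < 1e-12) {
    stop("dbtvr_domain_error: degenerate tap set (zero weight sum)", call. = FALSE)
  }
  structure(list(offsets = offsets, weights = w / total), class = "tap_set")
}
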