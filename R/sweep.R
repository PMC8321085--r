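#' The study's sampling-distance grid
#'
#' Twelve distances in mm: seven at or below the Nyquist bound of a 0.085 mm
#' grid (`2 * 0.085 = 0.170` mm), the empirical automatic distance 0.195 mm,
#' and four coarser values up to the renderer default of 1.0 mm.
#'
#' @return Numeric vector of 12 sampling distances (mm).
#' @export
default_sampling_distances <- function() {
  c(0.010, 0.025, 0.050, 0.075, 0.100, 0.145, 0.170, 0.195, 0.4, 0.6, 0.8, 1.0)
}

#' The study's interpolation-kernel grid
#'
#' The three plain interpolators, a window-half-width sweep (all seven
#' windows, `W` in 1, 3, 5, 8, 13, 16, at `B = 1`), and a z-blur-factor
#' sweep (all seven windows, `B` in 1.0, 1.5, 2.0, 2.5, 3.0, 4.0, at the
#' default `W = 3`): `3 + 42 + 42` cells.
#'
#' @return A data frame with columns `family`, `window`, `W`, `B` and a
#'   `sweep` label (`"interpolator"`, `"whw"`, `"bf"`).
#' @export
default_kernel_grid <- function() {
  windows <- c("lanczos", "kaiser", "cosine", "hann", "hamming", "blackman", "nuttall")
  plain <- data.frame(family = c("nearest", "linear", "cubic"),
                      window = NA_character_, W = NA_integer_, B = NA_real_,
                      sweep = "interpolator", stringsAsFactors = FALSE)
  whw <- expand.grid(window = windows, W = c(1L, 3L, 5L, 8L, 13L, 16L),
                     stringsAsFactors = FALSE)
  whw <- data.frame(family = "windowed_sinc", window = whw$window, W = whw$W,
                    B = 1.0, sweep = "whw", stringsAsFactors = FALSE)
  bf <- expand.grid(window = windows, B = c(1.0, 1.5, 2.0, 2.5, 3.0, 4.0),
                    stringsAsFactors = FALSE)
  bf <- data.frame(family = "windowed_sinc", window = bf$window, W = 3L,
                   B = bf$B, sweep = "bf", stringsAsFactors = FALSE)
  rbind(plain, whw, bf)
}

grid_row_to_spec <- function(row) {
  if (row$family == "windowed_sinc") {
    kernel_spec("windowed_sinc", window = row$window, W = row$W, B = row$B)
  } else {
    kernel_spec(row$family)
  }
}

#' Configuration for a rendering-quality sweep
#'
#' Bundles everything [run_sweep()] needs: the input volume (typically a
#' synthetic phantom from [generate_phantom()]), the kernels and sampling
#' distances to cross, and the measurement geometry. The transfer function is
#' built once from the input volume's range and held fixed across all cells
#' so that metric differences reflect the parameters under study, not the
#' color mapping.
#'
#' @param volume A [tomo_volume]; if it carries a phantom spec attribute the
#'   measurement geometry defaults below are derived from it.
#' @param kernels Data frame as from [default_kernel_grid()] (subset rows to
#'   shrink the study), or a list of [kernel_spec]s.
#' @param sampling_distances Numeric vector of distances (mm).
#' @param include_original Also measure the unresampled volume (default TRUE).
#' @param new_sz Target slice spacing for resampling (default: the in-plane
#'   spacing, making the grid isotropic).
#' @param azimuths Subset of `c(90, 0)`; 90 is where the z-direction methods
#'   act, 0 adds the detector-parallel view used in the final comparison.
#' @param disk_center World-mm `(x, y, z)` center of the measured disk
#'   (default: the first and largest disk of the phantom spec).
#' @param disk_diameter Diameter (mm) of the measured disk (default from the
#'   phantom spec).
#' @param band_halfwidth Column band half-width (px) for profiles (default 5).
#' @param smoothness_window `z` window (mm) for the smoothness score.
#' @param roi_halfwidth_px Half-extent (px) of the square CNR ROIs (default 5,
#'   i.e. 11 x 11 px).
#' @param bg_offset_radii Background ROI offset from the disk center along
#'   `x`, in units of disk radii (default 1.5).
#' @param opacity_unit_distance Unit distance (mm) of the study's default
#'   transfer function. The default of 10 mm keeps the optical mean free path
#'   comparable to the object depth so the disks stay within view depth in
#'   both the 0- and 90-degree views; with much shorter unit distances the
#'   background becomes opaque over the 40 mm axial path and the 0-degree
#'   view never reaches the disk.
#' @param tf Optional [transfer_function] overriding the default.
#' @param seed Integer seed recorded with the config (the sweep itself is
#'   deterministic given its input volume).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(volume,
                         kernels = default_kernel_grid(),
                         sampling_distances = default_sampling_distances(),
                         include_original = TRUE,
                         new_sz = NULL,
                         azimuths = 90,
                         disk_center = NULL,
                         disk_diameter = NULL,
                         band_halfwidth = 5L,
                         smoothness_window = c(16, 24),
                         roi_halfwidth_px = 5L,
                         bg_offset_radii = 1.5,
                         opacity_unit_distance = 10.0,
                         tf = NULL,
                         seed = 1L) {
  stopifnot_volume(volume)
  if (is.data.frame(kernels)) {
    if (nrow(kernels) == 0L && !include_original) {
      stop("dbtvr_usage_error: empty kernel list", call. = FALSE)
    }
  } else if (length(kernels) == 0L && !include_original) {
    stop("dbtvr_usage_error: empty kernel list", call. = FALSE)
  }
  if (length(sampling_distances) == 0L || any(sampling_distances <= 0)) {
    stop("dbtvr_usage_error: sampling_distances must be non-empty and positive",
         call. = FALSE)
  }
  if (!all(azimuths %in% c(0, 90)) || length(azimuths) == 0L) {
    stop("dbtvr_usage_error: azimuths must be a subset of c(0, 90)", call. = FALSE)
  }
  pspec <- attr(volume, "spec")
  if (is.null(disk_center)) {
    if (is.null(pspec)) {
      stop("dbtvr_usage_error: disk_center required when the volume has no phantom spec",
           call. = FALSE)
    }
    disk_center <- pspec$disk_centers[1, ]
  }
  if (is.null(disk_diameter)) {
    disk_diameter <- if (!is.null(pspec)) pspec$disk_diameters[1] else 5.0
  }
  structure(list(volume = volume, kernels = kernels,
                 sampling_distances = as.double(sampling_distances),
                 include_original = isTRUE(include_original),
                 new_sz = new_sz %||% volume$spacing[1],
                 azimuths = azimuths,
                 disk_center = as.double(disk_center),
                 disk_diameter = as.double(disk_diameter),
                 band_halfwidth = as.integer(band_halfwidth),
                 smoothness_window = as.double(smoothness_window),
                 roi_halfwidth_px = as.integer(roi_halfwidth_px),
                 bg_offset_radii = as.double(bg_offset_radii),
                 tf = tf %||% default_transfer_function(volume, opacity_unit_distance),
                 seed = as.integer(seed)),
            class = "sweep_config")
}

# CNR ROIs for one image: disk ROI at the disk center, two background ROIs
# flanking it in x at +/- bg_offset_radii * radius, same second-axis band
sweep_rois <- function(img, cfg) {
  ax2 <- if (identical(img$axes, c("x", "z"))) 3L else 2L
  col0 <- round((cfg$disk_center[1] - img$axis_origin[1]) / img$pixel_spacing[1]) + 1
  row0 <- round((cfg$disk_center[ax2] - img$axis_origin[2]) / img$pixel_spacing[2]) + 1
  dx_px <- round(cfg$bg_offset_radii * (cfg$disk_diameter / 2) / img$pixel_spacing[1])
  h <- cfg$roi_halfwidth_px
  list(disk = roi_spec(c(row0, col0), c(h, h), "disk"),
       bg1 = roi_spec(c(row0, col0 - dx_px), c(h, h), "background"),
       bg2 = roi_spec(c(row0, col0 + dx_px), c(h, h), "background"))
}

# profile along x (columns) through the disk's row, limited to a window in x
# around the measured disk so neighbouring disks of the column stay out of the
# fit; used for the 0-degree FWHM
x_profile <- function(img, center_row_mm, band_halfwidth,
                      center_x_mm = NULL, x_halfwidth_mm = Inf) {
  row0 <- round((center_row_mm - img$axis_origin[2]) / img$pixel_spacing[2]) + 1
  rows <- (row0 - band_halfwidth):(row0 + band_halfwidth)
  if (rows[1] < 1 || rows[length(rows)] > nrow(img$pixels)) {
    stop("dbtvr_geometry_error: row band exceeds the image", call. = FALSE)
  }
  x_mm <- img$axis_origin[1] + (seq_len(ncol(img$pixels)) - 1) * img$pixel_spacing[1]
  y <- as.double(colMeans(img$pixels[rows, , drop = FALSE]))
  if (is.finite(x_halfwidth_mm) && !is.null(center_x_mm)) {
    keep <- abs(x_mm - center_x_mm) <= x_halfwidth_mm
    x_mm <- x_mm[keep]
    y <- y[keep]
  }
  list(z_mm = x_mm, intensity = y)
}

measure_image_90 <- function(img, cfg) {
  prof <- extract_profile(img, cfg$disk_center[1], cfg$band_halfwidth)
  rois <- sweep_rois(img, cfg)
  cn <- cnr(img, rois$disk, rois$bg1, rois$bg2, detail = TRUE)
  list(fwhm = fit_fwhm(prof),
       smoothness = smoothness(prof, cfg$smoothness_window, on_collinear = "inf"),
       cnr = cn)
}

measure_image_0 <- function(img, cfg) {
  prof <- x_profile(img, cfg$disk_center[2], cfg$band_halfwidth,
                    center_x_mm = cfg$disk_center[1],
                    x_halfwidth_mm = cfg$disk_diameter / 2 + 2.0)
  rois <- sweep_rois(img, cfg)
  cn <- cnr(img, rois$disk, rois$bg1, rois$bg2, detail = TRUE)
  list(fwhm = fit_fwhm(prof), cnr = cn)
}

#' Run the interpolation / sampling-distance sweep
#'
#' For every kernel (plus, optionally, the unresampled original volume) the
#' input is resampled along z once, then rendered at every requested sampling
#' distance and azimuth; each 90-degree image yields the disk profile, its
#' Gaussian-fit FWHM, the smoothness score and the CNR, and each 0-degree
#' image an in-plane FWHM and CNR. Wall times for interpolation and rendering
#' are recorded (monotonic clock) but never used in automated selection.
#' Deterministic: identical config (including its input volume) gives
#' identical records.
#'
#' @param cfg A [sweep_config].
#' @param verbose Print one line per kernel (default FALSE).
#' @return A data frame with one row per (kernel, sampling distance) cell:
#'   kernel identity columns, `d`, `fwhm_90`, `cnr_90`, `smoothness_90`,
#'   `mu_disk_90`, `mu_bg_90`, `sigma_bg_90`, optional `fwhm_0`/`cnr_0`, and
#'   `t_interp`/`t_render` in seconds.
#' @export
run_sweep <- function(cfg, verbose = FALSE) {
  if (!inherits(cfg, "sweep_config")) {
    stop("dbtvr_usage_error: expected a `sweep_config`", call. = FALSE)
  }
  # cells are keyed by kernel id *and* sweep label: the B-sweep's B=1 cells
  # coincide with the W-sweep's W=3 cells as kernels but belong to both sweeps
  kernel_list <- list()
  if (cfg$include_original) {
    kernel_list[["original"]] <- list(id = "original", spec = NULL,
                                      sweep = "original")
  }
  if (is.data.frame(cfg$kernels)) {
    for (i in seq_len(nrow(cfg$kernels))) {
      row <- cfg$kernels[i, ]
      sp <- grid_row_to_spec(row)
      sw <- row$sweep %||% NA_character_
      key <- paste(kernel_id(sp), sw, sep = "@")
      kernel_list[[key]] <- list(id = kernel_id(sp), spec = sp, sweep = sw)
    }
  } else {
    for (sp in cfg$kernels) {
      kernel_list[[kernel_id(sp)]] <- list(id = kernel_id(sp), spec = sp,
                                           sweep = NA_character_)
    }
  }

  rows <- list()
  for (key in names(kernel_list)) {
    entry <- kernel_list[[key]]
    kid <- entry$id
    if (is.null(entry$spec)) {
      vol_k <- cfg$volume
      t_interp <- 0
    } else {
      t0 <- proc.time()[["elapsed"]]
      vol_k <- resample_z(cfg$volume, cfg$new_sz, entry$spec)
      t_interp <- proc.time()[["elapsed"]] - t0
    }
    if (verbose) message(sprintf("kernel %-22s interp %.2fs", kid, t_interp))
    for (d in cfg$sampling_distances) {
      rec <- list(kernel = kid,
                  family = if (is.null(entry$spec)) "original" else entry$spec$family,
                  window = if (is.null(entry$spec)) NA_character_ else entry$spec$window,
                  W = if (is.null(entry$spec)) NA_integer_ else entry$spec$W,
                  B = if (is.null(entry$spec)) NA_real_ else entry$spec$B,
                  sweep = entry$sweep, d = d, t_interp = t_interp)
      t_render <- 0
      for (az in cfg$azimuths) {
        rc <- render_config(azimuth = az, sampling_distance = d, tf = cfg$tf)
        t0 <- proc.time()[["elapsed"]]
        img <- render(vol_k, rc)
        t_render <- t_render + proc.time()[["elapsed"]] - t0
        if (az == 90) {
          m <- measure_image_90(img, cfg)
          rec$fwhm_90 <- m$fwhm
          rec$smoothness_90 <- m$smoothness
          rec$cnr_90 <- m$cnr$cnr
          rec$mu_disk_90 <- m$cnr$mu_disk
          rec$mu_bg_90 <- m$cnr$mu_bg
          rec$sigma_bg_90 <- m$cnr$sigma_bg
        } else {
          m <- measure_image_0(img, cfg)
          rec$fwhm_0 <- m$fwhm
          rec$cnr_0 <- m$cnr$cnr
        }
      }
      rec$t_render <- t_render
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Select window half-width, blur factor and window function from sweep records
#'
#' Implements the study's selection rules on the two windowed-sinc sweeps:
#'
#' * `chosen_whw`: the smallest `W` whose mean smoothness (across windows) is
#'   within a tolerance `eps_s` (fraction of the maximum) of the best mean
#'   smoothness over `W` — i.e. the start of the smoothness plateau, the
#'   cheapest setting with no significant smoothness left to gain.
#' * `chosen_bf`: the smallest `B` at which the marginal relative decrease of
#'   mean FWHM to the next swept `B` falls below `fwhm_drop_tol` — the point
#'   where further blurring no longer buys definition.
#' * `chosen_window`: windows are ranked by smoothness (descending) under the
#'   chosen `W` (at `B = 1`) and under the chosen `B` (at `W = 3`); the
#'   selected window is the best common performer, the one minimizing its
#'   worse rank of the two (ties by rank sum, then alphabetically).
#'
#' If no plateau exists (smoothness still rising at the largest swept `W`),
#' the largest value is chosen and flagged.
#'
#' @param records Data frame from [run_sweep()] covering a `W` sweep and a
#'   `B` sweep.
#' @param eps_s Plateau tolerance as a fraction of the maximum mean
#'   smoothness (default 0.02).
#' @param fwhm_drop_tol Marginal relative FWHM decrease below which larger
#'   `B` is not worth it (default 0.05).
#' @return A list of class `selection_report`: `chosen_whw`, `chosen_bf`,
#'   `chosen_window`, `window_ranking`, `flagged`, and the per-level
#'   criterion values in `justification`.
#' @export
select_parameters <- function(records, eps_s = 0.02, fwhm_drop_tol = 0.05) {
  ws <- records[records$family == "windowed_sinc" & records$sweep == "whw", ]
  bs <- records[records$family == "windowed_sinc" & records$sweep == "bf", ]
  if (nrow(ws) == 0L || nrow(bs) == 0L) {
    stop("dbtvr_usage_error: records must cover both a W sweep and a B sweep",
         call. = FALSE)
  }
  smooth_by_w <- tapply(ws$smoothness_90, ws$W, mean)
  w_levels <- as.integer(names(smooth_by_w))
  best <- max(smooth_by_w)
  ok <- smooth_by_w >= best * (1 - eps_s)
  chosen_whw <- min(w_levels[ok])
  flagged_w <- chosen_whw == max(w_levels) && length(w_levels) > 1L

  fwhm_by_b <- tapply(bs$fwhm_90, bs$B, mean)
  b_levels <- as.double(names(fwhm_by_b))
  ord <- order(b_levels)
  b_levels <- b_levels[ord]; fwhm_by_b <- fwhm_by_b[ord]
  chosen_bf <- b_levels[length(b_levels)]
  flagged_b <- TRUE
  for (i in seq_len(length(b_levels) - 1L)) {
    drop_rel <- (fwhm_by_b[i] - fwhm_by_b[i + 1]) / fwhm_by_b[i]
    if (drop_rel < fwhm_drop_tol) {
      chosen_bf <- b_levels[i]
      flagged_b <- FALSE
      break
    }
  }

  rank_in <- function(df) {
    sm <- tapply(df$smoothness_90, df$window, mean)
    rk <- rank(-sm, ties.method = "average")
    rk[order(names(rk))]
  }
  r1 <- rank_in(ws[ws$W == chosen_whw, ])
  r2 <- rank_in(bs[bs$B == chosen_bf, ])
  common <- intersect(names(r1), names(r2))
  worst <- pmax(r1[common], r2[common])
  total <- r1[common] + r2[common]
  ordc <- order(worst, total, common)
  ranking <- common[ordc]

  structure(list(chosen_whw = chosen_whw, chosen_bf = chosen_bf,
                 chosen_window = ranking[1], window_ranking = ranking,
                 flagged = c(whw = flagged_w, bf = flagged_b),
                 justification = list(smoothness_by_whw = as.list(smooth_by_w),
                                      fwhm_by_bf = as.list(fwhm_by_b),
                                      rank_at_whw = as.list(r1),
                                      rank_at_bf = as.list(r2),
                                      eps_s = eps_s,
                                      fwhm_drop_tol = fwhm_drop_tol)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> W = %d, B = %g, window = %s\n",
              x$chosen_whw, x$chosen_bf, x$chosen_window))
  cat("  ranking:", paste(x$window_ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Percent change between two measurements
#'
#' `100 * (after - before) / before`: negative for a decrease. This is the
#' arithmetic behind summary claims such as "a ~67% decrease in FWHM".
#'
#' @param before Baseline value, non-zero.
#' @param after New value.
#' @return Percent change.
#' @examples
#' percent_change(12.38, 4.06)
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) {
    stop("dbtvr_domain_error: percent change undefined for before = 0", call. = FALSE)
  }
  100 * (after - before) / before
}

#' Default-vs-optimized comparison table from sweep records
#'
#' Pulls two cells out of a record table and lays their metrics side by side
#' with the percent change, in the shape of the study's final summary table.
#'
#' @param records Data frame from [run_sweep()].
#' @param default_kernel,default_d Identity of the baseline cell (defaults:
#'   the unresampled volume at 1.0 mm).
#' @param optimized_kernel,optimized_d Identity of the optimized cell.
#' @return Data frame with columns `metric`, `default`, `optimized`,
#'   `pct_change`.
#' @export
comparison_table <- function(records,
                             default_kernel = "original", default_d = 1.0,
                             optimized_kernel, optimized_d) {
  pick <- function(kernel, d) {
    row <- records[records$kernel == kernel & abs(records$d - d) < 1e-12, ]
    if (nrow(row) != 1L) {
      stop(sprintf("dbtvr_usage_error: no unique record for (%s, d = %g)", kernel, d),
           call. = FALSE)
    }
    row
  }
  a <- pick(default_kernel, default_d)
  b <- pick(optimized_kernel, optimized_d)
  metrics <- intersect(c("cnr_0", "fwhm_0", "cnr_90", "fwhm_90", "smoothness_90"),
                       names(records))
  data.frame(metric = metrics,
             default = as.double(a[1, metrics]),
             optimized = as.double(b[1, metrics]),
             pct_change = vapply(metrics, function(m) {
               percent_change(a[[m]], b[[m]])
             }, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble (and optionally write) the full study report
#'
#' Collects the record table, the selection report, a default-vs-optimized
#' comparison and the standard trend figures (smoothness and FWHM vs `W`,
#' `B`, and sampling distance) into one object. If `out_dir` is given the
#' pieces are written as `records.csv`, `selection.json`, `comparison.csv`,
#' `report.md` and `figures/*.png`.
#'
#' @param records Data frame from [run_sweep()].
#' @param selection Optional [select_parameters()] result.
#' @param comparison Optional [comparison_table()] result.
#' @param out_dir Optional output directory.
#' @return A list of class `study_report` (invisibly when writing).
#' @export
study_report <- function(records, selection = NULL, comparison = NULL,
                         out_dir = NULL) {
  records <- as_records_df(records)
  figures <- trend_figures(records)
  report <- structure(list(records = records, selection = selection,
                           comparison = comparison, figures = figures),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(records, file.path(out_dir, "records.csv"))
    if (!is.null(selection)) {
      jsonlite::write_json(selection[c("chosen_whw", "chosen_bf", "chosen_window",
                                       "window_ranking", "justification")],
                           file.path(out_dir, "selection.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    if (!is.null(comparison)) {
      write_results_csv(comparison, file.path(out_dir, "comparison.csv"))
    }
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    for (nm in names(figures)) {
      try(ggplot2::ggsave(file.path(fig_dir, paste0(nm, ".png")), figures[[nm]],
                          width = 6, height = 4, dpi = 150), silent = TRUE)
    }
    writeLines(report_md(report), file.path(out_dir, "report.md"))
  }
  invisible(report)
}

trend_figures <- function(records) {
  figs <- list()
  ws <- records[records$family == "windowed_sinc" &
                  !is.na(records$sweep) & records$sweep == "whw", ]
  if (nrow(ws) > 0L) {
    figs$smoothness_vs_whw <- ggplot2::ggplot(ws,
        ggplot2::aes(x = W, y = smoothness_90, colour = window)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "window half-width (samples)", y = "smoothness (90°)")
    figs$fwhm_vs_whw <- ggplot2::ggplot(ws,
        ggplot2::aes(x = W, y = fwhm_90, colour = window)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "window half-width (samples)", y = "FWHM (mm, 90°)")
  }
  bs <- records[records$family == "windowed_sinc" &
                  !is.na(records$sweep) & records$sweep == "bf", ]
  if (nrow(bs) > 0L) {
    figs$smoothness_vs_bf <- ggplot2::ggplot(bs,
        ggplot2::aes(x = B, y = smoothness_90, colour = window)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "z blur factor", y = "smoothness (90°)")
    figs$fwhm_vs_bf <- ggplot2::ggplot(bs,
        ggplot2::aes(x = B, y = fwhm_90, colour = window)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "z blur factor", y = "FWHM (mm, 90°)")
  }
  if (length(unique(records$d)) > 1L) {
    figs$fwhm_vs_d <- ggplot2::ggplot(records,
        ggplot2::aes(x = d, y = fwhm_90, colour = kernel)) +
      ggplot2::geom_line() + ggplot2::geom_point() + ggplot2::scale_x_log10() +
      ggplot2::labs(x = "sampling distance (mm)", y = "FWHM (mm, 90°)")
    figs$smoothness_vs_d <- ggplot2::ggplot(records,
        ggplot2::aes(x = d, y = smoothness_90, colour = kernel)) +
      ggplot2::geom_line() + ggplot2::geom_point() + ggplot2::scale_x_log10() +
      ggplot2::labs(x = "sampling distance (mm)", y = "smoothness (90°)")
  }
  figs
}

report_md <- function(report) {
  lines <- c("# Rendering-quality study report", "")
  if (!is.null(report$selection)) {
    s <- report$selection
    lines <- c(lines,
               sprintf("Selected parameters: W = %d, B = %g, window = %s",
                       s$chosen_whw, s$chosen_bf, s$chosen_window),
               sprintf("Window ranking: %s", paste(s$window_ranking, collapse = " > ")),
               "")
  }
  if (!is.null(report$comparison)) {
    cmp <- report$comparison
    lines <- c(lines, "| metric | default | optimized | % change |",
               "|---|---|---|---|",
               sprintf("| %s | %.4g | %.4g | %+.1f |",
                       cmp$metric, cmp$default, cmp$optimized, cmp$pct_change),
               "")
  }
  lines <- c(lines, sprintf("Cells measured: %d", nrow(report$records)))
  lines
}
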