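test_that("the default grids reproduce the study's parameter tables exactly", {
  expect_identical(default_sampling_distances(),
                   c(0.010, 0.025, 0.050, 0.075, 0.100, 0.145, 0.170, 0.195,
                     0.4, 0.6, 0.8, 1.0))
  grid <- default_kernel_grid()
  expect_identical(nrow(grid), 87L)                 # 3 + 7*6 + 7*6
  expect_identical(sum(grid$sweep == "interpolator"), 3L)
  expect_identical(sum(grid$sweep == "whw"), 42L)
  expect_identical(sum(grid$sweep == "bf"), 42L)
  expect_setequal(unique(grid$window[grid$family == "windowed_sinc"]),
                  c("lanczos", "kaiser", "cosine", "hann", "hamming", "blackman",
                    "nuttall"))
  expect_setequal(unique(grid$W[grid$sweep == "whw"]), c(1, 3, 5, 8, 13, 16))
  expect_setequal(unique(grid$B[grid$sweep == "bf"]), c(1.0, 1.5, 2.0, 2.5, 3.0, 4.0))
  expect_true(all(grid$B[grid$sweep == "whw"] == 1))
  expect_true(all(grid$W[grid$sweep == "bf"] == 3))
})

test_that("a sweep cell yields one record and reruns reproduce it exactly", {
  vol <- generate_phantom(small_phantom_spec())
  cfg <- sweep_config(vol,
                      kernels = list(kernel_spec("windowed_sinc", window = "hamming",
                                                 W = 3, B = 2)),
                      sampling_distances = 0.4,
                      include_original = FALSE,
                      azimuths = c(90, 0),
                      band_halfwidth = 2L)
  rec <- run_sweep(cfg)
  expect_identical(nrow(rec), 1L)
  expect_true(all(c("kernel", "d", "fwhm_90", "cnr_90", "smoothness_90",
                    "fwhm_0", "cnr_0", "t_interp", "t_render") %in% names(rec)))
  expect_gt(rec$fwhm_90, 0)
  expect_gt(rec$sigma_bg_90, 0)

  rec2 <- run_sweep(cfg)
  metric_cols <- setdiff(names(rec), c("t_interp", "t_render"))
  expect_identical(rec[metric_cols], rec2[metric_cols])
})

test_that("sweep records carry cell identity for each kernel and distance", {
  vol <- generate_phantom(small_phantom_spec())
  grid <- default_kernel_grid()
  grid <- grid[grid$family %in% c("nearest", "linear"), ]
  cfg <- sweep_config(vol, kernels = grid, sampling_distances = c(0.4, 1.0),
                      include_original = TRUE, band_halfwidth = 2L)
  rec <- run_sweep(cfg)
  expect_identical(nrow(rec), 6L)                   # (original + 2 kernels) x 2 d
  expect_setequal(unique(rec$kernel), c("original", "nearest", "linear"))
  expect_setequal(unique(rec$d), c(0.4, 1.0))

  # the W-sweep's W=3 and the B-sweep's B=1 cells are the same kernel but
  # distinct sweep cells: both must be present in the records
  grid2 <- default_kernel_grid()
  grid2 <- grid2[grid2$window %in% "hamming" &
                   ((grid2$sweep == "whw" & grid2$W == 3) |
                      (grid2$sweep == "bf" & grid2$B == 1)), ]
  cfg2 <- sweep_config(vol, kernels = grid2, sampling_distances = 1.0,
                       include_original = FALSE, band_halfwidth = 2L)
  rec2 <- run_sweep(cfg2)
  expect_identical(nrow(rec2), 2L)
  expect_identical(unique(rec2$kernel), "hamming_W3_B1")
  expect_setequal(rec2$sweep, c("whw", "bf"))
})

test_that("parameter selection finds plateaus and flags their absence", {
  synth <- function(W, B, smooth, fwhm, sweep) {
    n <- max(length(W), length(B), length(smooth))
    data.frame(kernel = sprintf("w%d_b%g", rep(W, length.out = n),
                                rep(B, length.out = n)),
               family = "windowed_sinc",
               window = rep(c("hamming", "hann"), each = n / 2),
               W = rep(W, length.out = n), B = rep(B, length.out = n),
               sweep = sweep, d = 1,
               fwhm_90 = rep(fwhm, length.out = n),
               smoothness_90 = rep(smooth, length.out = n),
               stringsAsFactors = FALSE)
  }
  Ws <- rep(c(1, 3, 5, 8, 13, 16), times = 2)
  # smoothness plateaus exactly at W = 5
  sm_w <- rep(c(40, 70, 100, 100.5, 100.2, 100.4), times = 2)
  ws <- synth(Ws, 1, sm_w, 8, "whw")
  Bs <- rep(c(1, 1.5, 2, 2.5, 3, 4), times = 2)
  # FWHM: marked decrease up to B = 2, then flat
  fw_b <- rep(c(10, 9, 8.2, 8.15, 8.12, 8.1), times = 2)
  bs <- synth(3, Bs, seq(50, 105, length.out = 12), fw_b, "bf")
  sel <- select_parameters(rbind(ws, bs))
  expect_identical(sel$chosen_whw, 5L)
  expect_identical(sel$chosen_bf, 2)
  expect_false(any(sel$flagged))

  # strictly increasing smoothness with no plateau: largest W, flagged
  ws2 <- synth(Ws, 1, rep(c(10, 30, 50, 70, 90, 110), times = 2), 8, "whw")
  sel2 <- select_parameters(rbind(ws2, bs))
  expect_identical(sel2$chosen_whw, 16L)
  expect_true(sel2$flagged[["whw"]])

  expect_error(select_parameters(ws), "W sweep and a B sweep")
})

test_that("window ranking picks the best common performer and survives eps jitter", {
  windows <- c("lanczos", "kaiser", "hamming", "hann")
  mk <- function(W, B, sweep, smooth) {
    data.frame(kernel = paste0(windows, W, B), family = "windowed_sinc",
               window = windows, W = W, B = B, sweep = sweep, d = 1,
               fwhm_90 = c(9, 8.5, 8.6, 8.8), smoothness_90 = smooth,
               stringsAsFactors = FALSE)
  }
  recs <- list()
  for (W in c(1, 3, 5, 8, 13, 16)) {
    base <- c(80, 96, 95, 70) * (0.5 + 0.5 * min(W, 5) / 5)
    recs[[length(recs) + 1]] <- mk(W, 1, "whw", base)
  }
  for (B in c(1, 1.5, 2, 2.5, 3, 4)) {
    # under the B sweep kaiser collapses, hamming stays near the top
    base <- c(90, 60, 97, 88) * (0.6 + 0.1 * B)
    recs[[length(recs) + 1]] <- mk(3, B, "bf", base)
  }
  records <- do.call(rbind, recs)
  for (eps in c(0.018, 0.02, 0.022)) {              # +/- 10% around the default
    sel <- select_parameters(records, eps_s = eps)
    expect_identical(sel$chosen_window, "hamming", label = sprintf("eps %g", eps))
  }
})

test_that("percent change reproduces the published summary arithmetic", {
  ref <- reference_comparison()
  pc <- function(metric) {
    percent_change(ref$default[ref$metric == metric],
                   ref$optimized[ref$metric == metric])
  }
  expect_equal(pc("fwhm_90"), -67.2, tolerance = 0.01)
  expect_equal(pc("smoothness_90"), 126.7, tolerance = 0.05)
  expect_gt(pc("cnr_90"), 500)
  expect_equal(pc("fwhm_0"), -4.1, tolerance = 0.01)
  expect_identical(percent_change(3, 3), 0)
  expect_error(percent_change(0, 1), "undefined")
})

test_that("study reports round-trip through their saved CSV", {
  vol <- generate_phantom(small_phantom_spec())
  cfg <- sweep_config(vol,
                      kernels = list(kernel_spec("linear"),
                                     kernel_spec("windowed_sinc", window = "hamming",
                                                 W = 3, B = 2)),
                      sampling_distances = c(0.4, 1.0), band_halfwidth = 2L)
  rec <- run_sweep(cfg)
  cmp <- comparison_table(rec, optimized_kernel = "hamming_W3_B2", optimized_d = 0.4)
  expect_identical(cmp$metric, c("cnr_90", "fwhm_90", "smoothness_90"))
  expect_equal(cmp$pct_change[cmp$metric == "fwhm_90"],
               percent_change(rec$fwhm_90[rec$kernel == "original" & rec$d == 1],
                              rec$fwhm_90[rec$kernel == "hamming_W3_B2" & rec$d == 0.4]))

  out <- withr::local_tempdir()
  rep1 <- study_report(rec, comparison = cmp, out_dir = out)
  expect_true(file.exists(file.path(out, "records.csv")))
  expect_true(file.exists(file.path(out, "report.md")))
  back <- read_results_csv(file.path(out, "records.csv"))
  rep2 <- study_report(back, comparison = cmp)
  num <- vapply(rep1$records, is.numeric, logical(1))
  for (nm in names(rep1$records)[num]) {
    expect_equal(rep2$records[[nm]], rep1$records[[nm]], tolerance = 1e-9, info = nm)
  }
  # the full sampling-distance grid stays intact in a report built on it
  expect_identical(sort(unique(rep1$records$d)), c(0.4, 1.0))
})
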