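test_that("moving-average subtraction follows the windowing rules", {
  cfg <- scan_config(frame_count = 100, image_size = 8)
  set.seed(21)
  counts <- array(rpois(100 * 64, 5), dim = c(100, 8, 8))
  rs <- raster_series(counts, cfg)
  flt <- subtract_moving_average(rs, window = 10)
  expect_equal(dim(flt$counts)[1], 90)          # first/last 5 frames dropped
  # retained frame 11 of the filtered series corresponds to original frame
  # 16 (1-based): its subtrahend is the mean of original frames 11..21
  k <- 11
  orig <- 16
  expected <- counts[orig, , ] - apply(counts[11:21, , ], c(2, 3), mean) +
    mean(counts)
  expect_equal(flt$counts[k, , ], expected, tolerance = 1e-12)
  # temporally constant series maps to the constant itself
  const <- raster_series(array(7L, dim = c(40, 8, 8)), cfg)
  fc <- subtract_moving_average(const)
  expect_true(all(abs(fc$counts - 7) < 1e-12))
  expect_error(subtract_moving_average(rs, window = 100), "smaller")
})

test_that("FFT autocorrelation equals the direct shifted-product sum", {
  set.seed(22)
  cfg <- scan_config(frame_count = 12, image_size = 16)
  counts <- array(rpois(12 * 256, 4) + rep(round(3 * sin(1:256 / 9)^2),
                                           each = 12),
                  dim = c(12, 16, 16))
  rs <- raster_series(counts, cfg)
  acf <- compute_acf(rs)
  # independent oracle: direct O(n^4) average of shifted products per frame
  direct <- 0
  for (f in 1:12) {
    fr <- matrix(counts[f, , ], 16, 16)
    dI <- fr - mean(fr)
    direct <- direct + acf_direct_frame_cpp(dI, 4L, 4L) / mean(fr)^2 / 12
  }
  expect_lt(max(abs(acf$values - direct) / max(abs(direct))), 1e-10)
})

test_that("the ACF is symmetric and near zero for white noise", {
  set.seed(23)
  cfg <- scan_config(frame_count = 20, image_size = 32)
  rs <- raster_series(array(rpois(20 * 1024, 6), dim = c(20, 32, 32)), cfg)
  acf <- compute_acf(rs)
  expect_equal(acf$values, acf$values[rev(seq_along(acf$psi)),
                                      rev(seq_along(acf$xi))],
               tolerance = 1e-12)
  offcentre <- acf$values
  offcentre[acf$psi == 0, acf$xi == 0] <- NA
  expect_lt(max(abs(offcentre), na.rm = TRUE), 0.02)
  expect_gt(acf$G0, 0.1)   # the shot-noise spike sits at zero lag
})

test_that("ROI selection is honoured and validated", {
  set.seed(24)
  cfg <- scan_config(frame_count = 10, image_size = 32)
  counts <- array(rpois(10 * 1024, 5), dim = c(10, 32, 32))
  rs <- raster_series(counts, cfg)
  a_roi <- compute_acf(rs, roi = c(8, 8, 16))
  a_sub <- compute_acf(raster_series(counts[, 9:24, 9:24, drop = FALSE],
                                     cfg))
  expect_equal(a_roi$values, a_sub$values, tolerance = 1e-12)
  expect_error(compute_acf(rs, roi = c(20, 20, 16)), "outside")
})

test_that("diffusion is recovered and monotone in the truth", {
  # recovery at the free-GFP-like rate
  D_hat <- recover_D(6.33, seed = 25)
  expect_equal(D_hat, 6.33, tolerance = 0.15)
  # monotonicity over a 2x ladder at a shared seed
  ladder <- vapply(c(1, 2, 4, 8), recover_D, numeric(1), seed = 26)
  expect_true(all(diff(ladder) > 0))
})

test_that("immobile-only series fit to a vanishing amplitude", {
  set.seed(27)
  cfg <- scan_config(frame_count = 40, image_size = 48)
  psf <- psf_model(0.25)
  sp <- species_spec("imm", 0, 3, count = 150)
  rs <- synthesize_raster(sp, psf, cfg, background_rate = 0.2)
  fit <- fit_diffusion(compute_acf(subtract_moving_average(rs)), psf)
  expect_lt(fit$G0, 0.05)
})

test_that("the QC rule compares the ACF maximum to the worst residual", {
  set.seed(28)
  rs <- make_raster(6.33, seed = 28, config = rics_test_config(image = 64))
  acf <- compute_acf(subtract_moving_average(rs))
  fit <- fit_diffusion(acf, psf_model(0.25))
  expect_true(fit$qc_pass)
  expect_true(max(acf$values) >= 3 * max(abs(fit$residuals[
    !(row(fit$residuals) == (length(acf$psi) + 1) / 2 &
        col(fit$residuals) == (length(acf$xi) + 1) / 2)])))
  # corrupt the surface so no one-component model fits: qc must fail
  bad <- acf
  set.seed(1)
  bad$values <- bad$values + matrix(rnorm(length(bad$values),
                                          sd = max(bad$values) / 2),
                                    nrow(bad$values))
  fit_bad <- fit_diffusion(bad, psf_model(0.25))
  expect_false(fit_bad$qc_pass)
})

test_that("PSF calibration recovers the waist and G0 scales as 1/N", {
  cal_cfg <- scan_config(pixel_size = 0.05, pixel_dwell = 12.61,
                         line_time = 1.0, frame_count = 30, image_size = 64)
  gen <- function(seed, count) {
    set.seed(seed)
    sp <- species_spec("egfp", 78, 2, count = count)
    synthesize_raster(sp, psf_model(0.25), cal_cfg, background_rate = 0.05)
  }
  ps <- calibrate_psf(gen(29, 150))
  expect_equal(ps$w0, 0.25, tolerance = 0.10)
  ps_half <- calibrate_psf(gen(30, 75))
  expect_equal(attr(ps_half, "G0") / attr(ps, "G0"), 2, tolerance = 0.35)
  expect_error(calibrate_psf(gen(31, 150), fixed_D = -1), "positive")
})
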