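test_that("pure Poisson counts sit at B = 1, N = <k>", {
  set.seed(41)
  counts <- array(rpois(100 * 48 * 48, 5), dim = c(100, 48, 48))
  bm <- brightness_map(counts, s_factor = 1, smooth_px = 1L)
  expect_equal(stats::median(bm$B, na.rm = TRUE), 1, tolerance = 0.02)
  expect_equal(mean(bm$N / bm$mean, na.rm = TRUE), 1, tolerance = 0.05)
  # zero-mean pixels are masked, not 0/0
  counts[, 1, 1] <- 0L
  bm2 <- brightness_map(counts, smooth_px = 1L)
  expect_true(is.na(bm2$B[1, 1]))
  expect_warning(brightness_map(counts[1:20, , ], smooth_px = 1L),
                 "30 frames")
})

test_that("S-factor calibration centres the background at B = 1 and is
           linear in the excess variance", {
  set.seed(42)
  bg <- array(rpois(80 * 40 * 40, 4), dim = c(80, 40, 40))
  s <- calibrate_sfactor(bg)
  expect_equal(s, 1, tolerance = 0.03)
  bm <- brightness_map(bg, s_factor = s, smooth_px = 1L)
  expect_equal(stats::median(bm$B, na.rm = TRUE), 1, tolerance = 0.02)
  # doubling the variance at fixed mean halves the s-factor
  doubled <- 2L * array(rpois(80 * 40 * 40, 2), dim = c(80, 40, 40))
  s2 <- calibrate_sfactor(doubled)
  expect_equal(s2, 0.5, tolerance = 0.03)
  expect_error(calibrate_sfactor(bg[, 1:10, 1:10]), "too small")
})

test_that("monomer and homodimer brightness scale as epsilon and 2 epsilon", {
  mono <- make_nandb_field(43, n_fluor = 1L, count = 4000L)
  dimer <- make_nandb_field(44, n_fluor = 2L, count = 2000L)
  bm_m <- brightness_map(mono, s_factor = 1)
  bm_d <- brightness_map(dimer, s_factor = 1)
  # background dilution is ~2% at these settings
  expect_equal(mean(bm_m$B, na.rm = TRUE) - 1, 0.28, tolerance = 0.08)
  expect_equal(mean(bm_d$B, na.rm = TRUE) - 1, 0.56, tolerance = 0.08)
  # halving the per-unit brightness halves epsilon-hat
  half <- make_nandb_field(45, eps = 0.14, count = 4000L)
  bm_h <- brightness_map(half, s_factor = 1)
  expect_equal((mean(bm_h$B, na.rm = TRUE) - 1) /
                 (mean(bm_m$B, na.rm = TRUE) - 1), 0.5, tolerance = 0.15)
})

test_that("measure_monomer recovers epsilon and rejects dimer mixtures", {
  mono <- make_nandb_field(46, n_fluor = 1L, count = 4000L)
  bm <- brightness_map(mono, s_factor = 1)
  cur <- measure_monomer(bm)
  expect_gt(cur$epsilon, 0.25)
  expect_lt(cur$epsilon, 0.31)
  # empty image errors
  set.seed(46)
  empty <- brightness_map(array(rpois(60 * 32 * 32, 0.05),
                                dim = c(60, 32, 32)), smooth_px = 1L)
  expect_error(measure_monomer(empty), "too few")
  # grossly bimodal map errors
  bimodal <- bm
  half_px <- seq_len(length(bimodal$B) %/% 2)
  bimodal$B[half_px] <- bimodal$B[half_px] + 0.6
  expect_error(measure_monomer(bimodal), "bimodal")
})

test_that("oligomer classification recovers segregated mixtures monotonically", {
  mono <- make_nandb_field(47, n_fluor = 1L, count = 4000L)
  dimer <- make_nandb_field(48, n_fluor = 2L, count = 2000L)
  bm_m <- brightness_map(mono, s_factor = 1)
  bm_d <- brightness_map(dimer, s_factor = 1)
  cur <- cursor_spec(0.28, 0.28)
  pure <- classify_oligomers(bm_m, cur)
  expect_equal(pure$pct_monomer, 100, tolerance = 0.04)
  expect_lt(pure$pct_dimer, 3)                  # false-dimer rate
  fracs <- c(0, 0.05, 0.10, 0.20)
  est <- vapply(seq_along(fracs), function(i) {
    classify_oligomers(composite_bmap(bm_m, bm_d, fracs[i], seed = i),
                       cur)$pct_dimer
  }, numeric(1))
  expect_true(all(diff(est) > 0))               # monotone in the truth
  mix <- classify_oligomers(composite_bmap(bm_m, bm_d, 0.075, seed = 9), cur)
  expect_gt(mix$pct_dimer, 5.5)
  expect_lt(mix$pct_dimer, 9.5)
  expect_error(classify_oligomers(bm_m, cursor_spec(0.1, 0.3)),
               "overlapping")
})

test_that("brightness is intensive: doubling concentration doubles N only", {
  lo <- make_nandb_field(49, count = 2000L)
  hi <- make_nandb_field(50, count = 4000L)
  bm_lo <- brightness_map(lo, s_factor = 1)
  bm_hi <- brightness_map(hi, s_factor = 1)
  expect_equal(mean(bm_hi$B, na.rm = TRUE) - 1,
               mean(bm_lo$B, na.rm = TRUE) - 1, tolerance = 0.06)
  expect_equal(mean(bm_hi$mean) / mean(bm_lo$mean), 2, tolerance = 0.1)
})

test_that("cross-brightness separates complexes, independence and
           anticorrelation", {
  cpl <- make_nandb_field(51, channels = "both",
                          species = make_mixture(0, 0, 1, 0, total = 3000L))
  cm <- cross_brightness(cpl$counts$green, cpl$counts$red)
  expect_gt(stats::median(cm$B_cc, na.rm = TRUE), 0.05)
  expect_gt(mean(cm$significant, na.rm = TRUE), 0.9)
  # independent channels: separate particle sets
  ind <- make_nandb_field(52, channels = "both", species = list(
    species_spec("g", 6.33, 0.28, count = 3000L),
    species_spec("r", 6.33, 0.34, n_fluorophores_green = 0L,
                 n_fluorophores_red = 1L, count = 3000L)))
  cmi <- cross_brightness(ind$counts$green, ind$counts$red)
  expect_equal(stats::median(cmi$B_cc, na.rm = TRUE), 0, tolerance = 0.01)
  expect_lt(mean(cmi$significant, na.rm = TRUE), 0.15)
  # anti-correlated intensities give negative cross-brightness
  set.seed(53)
  g <- array(rpois(60 * 32 * 32, 5), dim = c(60, 32, 32))
  r <- max(g) - g
  cma <- cross_brightness(g, r, detrend_window = 0L, smooth_px = 1L)
  expect_lt(stats::median(cma$B_cc, na.rm = TRUE), -0.001)
  expect_true(all(sign(cma$sigma_cc2) == sign(cma$B_cc), na.rm = TRUE))
  expect_error(cross_brightness(g, r[1:30, , ]), "identical shape")
})

test_that("complex stoichiometry recovers the 1:1 / 2:1 split", {
  c11 <- make_nandb_field(54, channels = "both",
                          species = make_mixture(0, 0, 1, 0, total = 3000L))
  c21 <- make_nandb_field(55, channels = "both",
                          species = make_mixture(0, 0, 0, 1, total = 1500L))
  maps <- function(rs) list(g = brightness_map(rs$counts$green),
                            r = brightness_map(rs$counts$red),
                            cc = cross_brightness(rs$counts$green,
                                                  rs$counts$red))
  m11 <- maps(c11); m21 <- maps(c21)
  cg <- cursor_spec(0.28, 0.28); cr <- cursor_spec(0.34, 0.34)
  pure <- complex_stoichiometry(m11$cc, m11$g, m11$r, cg, cr)
  expect_gt(pure$fraction_11, 95)
  # composite 85/15 field
  set.seed(56)
  idx <- sample(length(m11$g$B), round(0.152 * length(m11$g$B)))
  mixg <- m11$g; mixg$B[idx] <- m21$g$B[idx]
  mixr <- m11$r; mixr$B[idx] <- m21$r$B[idx]
  mixcc <- m11$cc
  mixcc$B_cc[idx] <- m21$cc$B_cc[idx]
  mixcc$significant[idx] <- m21$cc$significant[idx]
  mixcc$mean_g[idx] <- m21$cc$mean_g[idx]
  mixcc$mean_r[idx] <- m21$cc$mean_r[idx]
  st <- complex_stoichiometry(mixcc, mixg, mixr, cg, cr)
  expect_gt(st$fraction_21, 10)
  expect_lt(st$fraction_21, 20)
  expect_equal(st$fraction_11 + st$fraction_21, 100)
  # red-homodimer complexes absent from the reported classes
  expect_equal(st$histogram$n_pixels[st$histogram$red_units == 2][1] /
                 st$n_complexed, 0, tolerance = 0.02)
  # no cross-correlated pixels: warning with n = 0, not an error
  none <- m11$cc
  none$significant[] <- FALSE
  expect_warning(st0 <- complex_stoichiometry(none, m11$g, m11$r, cg, cr),
                 "no cross-correlated")
  expect_equal(st0$n_complexed, 0)
})
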