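test_that("Brownian steps satisfy the Einstein relation", {
  set.seed(11)
  geom <- geometry_spec(c(0, 50), c(0, 50), c(-25, 25))
  sp <- species_spec("egfp", 78, 0.3, count = 10)
  tr <- simulate_particles(sp, geom, total_time = 0.1, dt = 1e-6)
  # per-axis squared increments over all steps and particles (boundaries are
  # 50 um away, effectively free diffusion)
  for (axis in 1:3) {
    msd1 <- mean(diff(tr$positions[, , axis])^2)
    expect_equal(msd1, 2 * 78 * 1e-6, tolerance = 0.05)
  }
  # MSD at a 10-step lag
  lag <- 10L
  p <- tr$positions[, , 1]
  msd10 <- mean((p[seq(1, nrow(p) - lag), ] - p[seq(1 + lag, nrow(p)), ])^2)
  expect_equal(msd10, 2 * 78 * 1e-5, tolerance = 0.05)
})

test_that("zero-diffusion species stay put and impermeable walls contain", {
  set.seed(12)
  geom <- geometry_spec(c(0, 10), c(0, 10), c(-2, 2),
                        walls = data.frame(position = 5, p_f = 0, p_r = 0))
  frozen <- species_spec("imm", 0, 1, count = 5)
  tr <- simulate_particles(frozen, geom, total_time = 0.01, dt = 1e-4)
  expect_equal(max(abs(apply(tr$positions, c(2, 3), stats::sd))), 0)

  left <- species_spec("m", 5, 1, count = 40, region = list(x = c(0, 4.9)))
  tr2 <- simulate_particles(left, geom, total_time = 0.5, dt = 1e-4)
  expect_true(all(tr2$positions[, , 1] < 5))
})

test_that("one-way wall gives monotone right-side occupancy", {
  set.seed(13)
  geom <- geometry_spec(c(0, 10), c(0, 10), c(-2, 2),
                        walls = data.frame(position = 5, p_f = 1, p_r = 0))
  sp <- species_spec("m", 5, 1, count = 200, region = list(x = c(0, 4.9)))
  tr <- simulate_particles(sp, geom, total_time = 4, dt = 1e-3)
  occ_right <- rowMeans(tr$positions[, , 1] > 5)
  # coarse-grained occupancy is nondecreasing (individual steps cannot
  # return, so any decrease would be a wall leak)
  expect_true(all(diff(occ_right) >= 0))
  expect_gt(occ_right[length(occ_right)], 0.5)
})

test_that("dt too coarse for the wall spacing is rejected with the species", {
  geom <- geometry_spec(c(0, 4), c(0, 4), c(-2, 2),
                        walls = data.frame(position = 2, p_f = 1, p_r = 1))
  fast <- species_spec("speedy", 100, 1, count = 5)
  expect_error(simulate_particles(fast, geom, total_time = 0.1, dt = 1e-2),
               "speedy")
})

test_that("empty-field rendering is Poisson background", {
  set.seed(14)
  cfg <- scan_config(frame_count = 30, image_size = 32)
  geom <- default_geometry(cfg, psf_model(), "raster")
  sp <- species_spec("dark", 1, 0, count = 1)  # zero brightness
  tr <- simulate_particles(sp, geom,
                           total_time = cfg$frame_count * frame_time(cfg),
                           dt = cfg$line_time * 1e-3)
  rs <- render_raster_series(tr, psf_model(), cfg, background_rate = 3)
  expect_true(all(rs$counts >= 0))
  expect_true(is.integer(rs$counts))
  expect_equal(mean(rs$counts), 3, tolerance = 0.02)
  expect_equal(stats::var(as.numeric(rs$counts)) / mean(rs$counts), 1,
               tolerance = 0.05)
})

test_that("an immobile centred particle images as the PSF", {
  set.seed(15)
  cfg <- scan_config(frame_count = 40, image_size = 32, pixel_size = 0.05)
  psf <- psf_model(0.25)
  geom <- default_geometry(cfg, psf, "raster")
  centre <- 16 * cfg$pixel_size
  sp <- species_spec("imm", 0, 20, count = 1,
                     region = list(x = c(centre, centre),
                                   y = c(centre, centre), z = c(0, 0)))
  tr <- simulate_particles(sp, geom,
                           total_time = cfg$frame_count * frame_time(cfg),
                           dt = cfg$line_time * 1e-3)
  rs <- render_raster_series(tr, psf, cfg, background_rate = 0.01)
  img <- apply(rs$counts, c(2, 3), mean)
  peak_col <- which.max(colSums(img)) - 1L
  expect_equal(peak_col, 16L, tolerance = 1)
  # e^-2 radius: profile at 0.25 um (5 px) from centre is ~e^-2 of peak
  prof <- img[17, ]  # row through the particle (0-based row 16)
  ratio <- prof[17 + 5L] / prof[17]
  expect_equal(ratio, exp(-2), tolerance = 0.35)
})

test_that("homodimers fluctuate more than monomers at matched intensity", {
  # same total fluorophore count: 2000 monomers vs 1000 dimers
  mono <- make_nandb_field(16, n_fluor = 1L, count = 2000L, frames = 50L)
  dimer <- make_nandb_field(17, n_fluor = 2L, count = 1000L, frames = 50L)
  m_mono <- mean(mono$counts); m_dim <- mean(dimer$counts)
  expect_equal(m_dim / m_mono, 1, tolerance = 0.1)   # matched intensity
  var_ratio <- function(rs) {
    mom <- scanfcs:::.pixel_moments(rs$counts, 10L)
    mean(mom$var) / mean(mom$mean)
  }
  expect_gt(var_ratio(dimer), var_ratio(mono) * 1.1)
})

test_that("make_mixture conserves counts and fluorophore stoichiometry", {
  mix <- make_mixture(0, 0, 0.848, 0.152, total = 1000L)
  expect_equal(sum(vapply(mix, function(s) s$count, integer(1))), 1000L)
  g_units <- sum(vapply(mix, function(s)
    s$count * s$n_fluorophores_green, numeric(1)))
  r_units <- sum(vapply(mix, function(s)
    s$count * s$n_fluorophores_red, numeric(1)))
  expect_equal(g_units / r_units, 1.152, tolerance = 1e-6)

  single <- make_mixture(1, 0, 0, 0, total = 10L)
  expect_length(single, 1)
  expect_equal(single[[1]]$label, "monomer")
  expect_equal(single[[1]]$n_fluorophores_red, 0L)

  expect_error(make_mixture(-0.1, 1.1, 0, 0), "nonnegative")
  expect_error(make_mixture(0.5, 0.1, 0, 0), "sum to 1")
})

test_that("rendering is reproducible given the seed", {
  cfg <- scan_config(frame_count = 10, image_size = 24)
  gen <- function() {
    set.seed(99)
    sp <- species_spec("m", 4, 2, count = 30)
    synthesize_raster(sp, psf_model(), cfg)$counts
  }
  expect_identical(gen(), gen())
})

test_that("line rendering validates the wall position and flags drift", {
  cfg <- pcf_test_config(4000)
  psf <- psf_model(0.25)
  # wall at the line edge is rejected
  geom_bad <- geometry_spec(c(0, 3.2), c(-0.75, 0.75), c(-2.25, 2.25),
                            walls = data.frame(position = 0.05, p_f = 1,
                                               p_r = 1))
  set.seed(18)
  expect_error(synthesize_lines(species_spec("m", 4, 2, count = 10), psf,
                                cfg, geometry = geom_bad),
               "span the wall interior")
  set.seed(18)
  ser <- make_wall_series(1, 1, seed = 18, n_lines = 4000)
  expect_equal(dim(ser$counts), c(4000L, 32L))
  # injected drift raises the flag; none without
  set.seed(19)
  ser_drift <- synthesize_lines(species_spec("m", 4, 2, count = 30), psf,
                                cfg, drift = 0.4)
  expect_true(check_drift(ser_drift)$drift_flag)
  expect_false(check_drift(ser)$drift_flag)
})
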