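# Shared synthetic-data fixtures, generated in code at test time.

# Raster study conditions: recommended acquisition settings at a 128 px ROI.
rics_test_config <- function(frames = 50L, image = 128L, pixel = 0.05) {
  scan_config(pixel_size = pixel, pixel_dwell = 12.61, line_time = 7.56,
              frame_count = frames, image_size = image)
}

# Single-species raster series via the streaming generator.
make_raster <- function(D, seed, eps = 4, count = 250L,
                        config = rics_test_config(), psf = psf_model(0.25),
                        background = 0.1, n_fluor = 1L) {
  set.seed(seed)
  sp <- species_spec("sp", D, eps, n_fluorophores_green = n_fluor,
                     count = count)
  synthesize_raster(sp, psf, config, background_rate = background)
}

recover_D <- function(D, seed, ...) {
  rs <- make_raster(D, seed, ...)
  flt <- subtract_moving_average(rs)
  fit_diffusion(compute_acf(flt), rs$psf)$D
}

# N&B study conditions: 64 px field at 0.1 um pixels, 100 frames, low
# background so the apparent brightness is background-dilution free.
nandb_test_config <- function(frames = 100L) {
  scan_config(pixel_size = 0.1, pixel_dwell = 12.61, line_time = 7.56,
              frame_count = frames, image_size = 64L)
}

make_nandb_field <- function(seed, n_fluor = 1L, count = 4000L %/% n_fluor,
                             eps = 0.28, frames = 100L, bg = 0.02,
                             channels = "green", species = NULL) {
  set.seed(seed)
  cfg <- nandb_test_config(frames)
  psf <- psf_model(0.25)
  sp <- if (!is.null(species)) species else
    species_spec("sp", 6.33, eps, n_fluorophores_green = n_fluor,
                 count = count)
  synthesize_raster(sp, psf, cfg, background_rate = bg, channels = channels)
}

# pCF study conditions: 32 px line at 0.1 um pixels, 0.5 ms line period,
# a cell wall of finite thickness (two semi-permeable planes 0.3 um apart)
# centred at column 16, periodic x so a one-way wall sustains a steady
# circulating flux.
pcf_test_config <- function(n_lines = 2e5) {
  scan_config(pixel_size = 0.1, pixel_dwell = 12.61, line_time = 0.5,
              image_size = 32L, line_length = 32L, n_lines = n_lines)
}

make_wall_series <- function(p_f, p_r, seed, D = 6, eps = 8, count = 90L,
                             n_lines = 2e5, thickness = 0.3) {
  set.seed(seed)
  cfg <- pcf_test_config(n_lines)
  psf <- psf_model(0.25)
  wall_x <- 16 * cfg$pixel_size
  walls <- data.frame(position = wall_x + c(-1, 1) * thickness / 2,
                      p_f = p_f, p_r = p_r)
  geom <- geometry_spec(xlim = c(-6.4, 6.4), ylim = c(-0.75, 0.75),
                        zlim = c(-2.25, 2.25), walls = walls,
                        periodic_x = TRUE)
  synthesize_lines(species_spec("m", D, eps, count = count), psf, cfg,
                   geometry = geom, background_rate = 0.05)
}

# Null series for false-positive checks: pure detector noise, no
# fluorescent particles, so every column is independent.  (A wall-free
# series with mobile particles is NOT a null: molecules genuinely cross
# the imaginary boundary and an arch call there is correct.)
make_null_series <- function(seed, n_lines = 1e5, background = 2) {
  set.seed(seed)
  cfg <- pcf_test_config(n_lines)
  psf <- psf_model(0.25)
  geom <- geometry_spec(xlim = c(-6.4, 6.4), ylim = c(-0.75, 0.75),
                        zlim = c(-2.25, 2.25), periodic_x = TRUE)
  dark <- species_spec("dark", 6, 0, count = 1L)
  synthesize_lines(dark, psf, cfg, geometry = geom,
                   background_rate = background)
}

# Arch call at one pixel separation, computing only the columns the
# detector inspects.
arch_call <- function(ser, dr, direction, wall = 16L, ...) {
  cols <- max(0, wall - dr - 1):min(31, wall + dr + 1)
  carp <- pair_correlation(ser, dr, direction, columns = cols)
  detect_arch(carp, wall, ser, ...)
}

mi_calls <- function(ser, direction, wall = 16L) {
  vapply(c(5L, 7L, 9L), function(dr)
    as.integer(arch_call(ser, dr, direction, wall)), integer(1))
}

# Composite brightness map: fraction `frac` of pixels drawn from map_b
# (spatially segregated populations, mixed after per-map smoothing).
composite_bmap <- function(map_a, map_b, frac, seed = 1) {
  set.seed(seed)
  out <- map_a
  idx <- sample(length(map_a$B), round(frac * length(map_a$B)))
  out$B[idx] <- map_b$B[idx]
  out$mean[idx] <- map_b$mean[idx]
  out
}
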