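#' Acquisition settings for a raster or line scan
#'
#' Bundles the confocal acquisition metadata that every scanning-FCS
#' computation needs: pixel size, pixel dwell time, line period, number of
#' frames and image geometry.  Defaults correspond to the recommended imaging
#' conditions for RICS/N&B on a root confocal setup (0.05 um pixels, 12.61 us
#' dwell, 7.56 ms line period, 50 frames of 256x256 pixels; line mode uses a
#' 32-pixel line scanned 2e5 times).
#'
#' @param pixel_size pixel size in micrometers.
#' @param pixel_dwell pixel dwell time in microseconds.
#' @param line_time line period (start of one line to start of the next,
#'   i.e. including the retrace) in milliseconds.
#' @param frame_count number of frames in raster mode.
#' @param image_size image side length in pixels (square frames).
#' @param line_length number of pixels in a line scan.
#' @param n_lines number of line repetitions in line mode.
#' @return An object of class `scan_config`.
#' @examples
#' cfg <- scan_config(frame_count = 50)
#' frame_time(cfg)   # seconds per frame
#' @export
scan_config <- function(pixel_size = 0.05, pixel_dwell = 12.61,
                        line_time = 7.56, frame_count = 50L,
                        image_size = 256L, line_length = 32L,
                        n_lines = 2e5) {
  stopifnot(pixel_size > 0, pixel_dwell > 0, line_time > 0,
            frame_count > 0, image_size > 0, line_length > 0, n_lines > 0)
  # active scan time along a line cannot exceed the line period
  if (pixel_dwell * image_size > line_time * 1e3) {
    stop("pixel_dwell * image_size exceeds the line period: retrace time ",
         "would be negative", call. = FALSE)
  }
  if (pixel_dwell * line_length > line_time * 1e3) {
    stop("pixel_dwell * line_length exceeds the line period", call. = FALSE)
  }
  structure(list(pixel_size = pixel_size, pixel_dwell = pixel_dwell,
                 line_time = line_time, frame_count = as.integer(frame_count),
                 image_size = as.integer(image_size),
                 line_length = as.integer(line_length),
                 n_lines = as.integer(n_lines)),
            class = "scan_config")
}

#' @rdname scan_config
#' @param config a `scan_config`.
#' @export
frame_time <- function(config) config$image_size * config$line_time * 1e-3

#' @export
print.scan_config <- function(x, ...) {
  cat("scan_config:", x$image_size, "x", x$image_size, "px,",
      x$frame_count, "frames\n")
  cat("  pixel", x$pixel_size, "um | dwell", x$pixel_dwell, "us | line",
      x$line_time, "ms | frame", signif(frame_time(x), 4), "s\n")
  cat("  line mode:", x$line_length, "px x", x$n_lines, "lines\n")
  invisible(x)
}

#' 3D Gaussian point spread function
#'
#' The effective observation volume is modelled as a 3D Gaussian with lateral
#' e^-2 waist `w0` and axial waist `wz`.  Typical water-immersion confocal
#' values are w0 = 0.25 um with wz/w0 = 3.
#'
#' @param w0 lateral beam waist (um).
#' @param wz axial beam waist (um); defaults to `axial_ratio * w0`.
#' @param axial_ratio wz/w0 used when `wz` is missing.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(w0 = 0.25, wz = NULL, axial_ratio = 3) {
  if (is.null(wz)) wz <- axial_ratio * w0
  stopifnot(w0 > 0, wz >= w0)
  structure(list(w0 = w0, wz = wz), class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat("psf_model: w0 =", x$w0, "um, wz =", x$wz, "um\n")
  invisible(x)
}

#' PSF shape factor for per-pixel moment analysis
#'
#' For a 3D Gaussian observation profile the apparent molecular brightness
#' measured by moment (N&B) analysis is gamma times the peak count rate,
#' with gamma = 2^(-3/2).  Species brightness in this package is specified in
#' apparent (N&B) units, so the renderer divides by this factor.
#' @return the scalar 2^(-3/2).
#' @export
psf_gamma <- function() 2^(-3 / 2)

#' Fluorescent species for the Brownian-dynamics simulator
#'
#' @param label species name.
#' @param diffusion_coefficient diffusion coefficient in um^2/s (0 for an
#'   immobile fraction).
#' @param brightness_per_unit apparent molecular brightness per green
#'   fluorophore unit, in counts/dwell/molecule as measured by N&B (i.e. the
#'   B-1 a single unit produces).
#' @param brightness_red_per_unit apparent brightness per red fluorophore
#'   unit; defaults to the green value.
#' @param n_fluorophores_green,n_fluorophores_red number of green/red
#'   fluorophore units carried by one particle (a homodimer carries twice the
#'   units of its monomer).
#' @param count number of particles.
#' @param region optional start region, a list with elements `x`, `y`, `z`
#'   (each a length-2 range in um) overriding the domain for initial
#'   placement.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(label, diffusion_coefficient, brightness_per_unit,
                         n_fluorophores_green = 1L, n_fluorophores_red = 0L,
                         count = 100L, region = NULL,
                         brightness_red_per_unit = brightness_per_unit) {
  stopifnot(diffusion_coefficient >= 0, brightness_per_unit >= 0,
            brightness_red_per_unit >= 0,
            n_fluorophores_green >= 0, n_fluorophores_red >= 0, count >= 0)
  structure(list(label = label,
                 diffusion_coefficient = diffusion_coefficient,
                 brightness_per_unit = brightness_per_unit,
                 brightness_red_per_unit = brightness_red_per_unit,
                 n_fluorophores_green = as.integer(n_fluorophores_green),
                 n_fluorophores_red = as.integer(n_fluorophores_red),
                 count = as.integer(count), region = region),
            class = "species_spec")
}

#' Simulation geometry: domain bounds and semi-permeable walls
#'
#' Walls are planes of constant x (the scan axis).  A particle step crossing
#' a wall left-to-right is accepted with probability `p_f`, right-to-left with
#' probability `p_r`; rejected steps are reflected.  Domain faces reflect.
#'
#' @param xlim,ylim,zlim domain bounds in um (length-2 each).
#' @param walls data.frame with columns `position`, `p_f`, `p_r`, or NULL.
#' @param periodic_x wrap the x boundaries instead of reflecting.  A
#'   one-way wall on a periodic domain sustains a steady circulating flux,
#'   emulating continuous production upstream and removal downstream.
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(xlim, ylim, zlim, walls = NULL,
                          periodic_x = FALSE) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(zlim) == 2,
            xlim[2] > xlim[1], ylim[2] > ylim[1], zlim[2] > zlim[1])
  if (is.null(walls)) {
    walls <- data.frame(position = numeric(0), p_f = numeric(0),
                        p_r = numeric(0))
  }
  stopifnot(all(c("position", "p_f", "p_r") %in% names(walls)))
  if (nrow(walls)) {
    if (any(walls$position <= xlim[1] | walls$position >= xlim[2]))
      stop("wall positions must lie strictly inside the domain", call. = FALSE)
    if (any(walls$p_f < 0 | walls$p_f > 1 | walls$p_r < 0 | walls$p_r > 1))
      stop("wall permeabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(xlim = xlim, ylim = ylim, zlim = zlim, walls = walls,
                 periodic_x = isTRUE(periodic_x)),
            class = "geometry_spec")
}

#' Default scan geometry for a raster configuration
#'
#' A box covering the scanned field laterally and a slab of thickness 6*wz
#' (reflecting faces) axially, centred on the focal plane.
#' @param config a `scan_config`.
#' @param psf a `psf_model`.
#' @param mode `"raster"` or `"line"`.
#' @param walls optional wall table (see [geometry_spec()]).
#' @export
default_geometry <- function(config, psf, mode = c("raster", "line"),
                             walls = NULL) {
  mode <- match.arg(mode)
  nx <- if (mode == "raster") config$image_size else config$line_length
  ny <- if (mode == "raster") config$image_size else 1L
  lx <- nx * config$pixel_size
  # keep the line-mode lateral reservoir thin so particles stay near the line
  ylim <- if (mode == "raster") c(0, ny * config$pixel_size) else
    c(-3, 3) * psf$w0
  geometry_spec(xlim = c(0, lx), ylim = ylim,
                zlim = c(-3 * psf$wz, 3 * psf$wz), walls = walls)
}
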