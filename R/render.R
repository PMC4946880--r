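#' Render a raster-scan photon-count series from particle trajectories
#'
#' Emulates confocal raster acquisition: pixel (frame, row, col) is acquired
#' at `frame*frame_time + row*line_time + col*pixel_dwell` and its photon
#' count is Poisson with mean
#' `background_rate + sum_p eps_p/gamma * exp(-2*dr^2/w0^2 - 2*dz^2/wz^2)`
#' evaluated at the particle positions interpolated to that acquisition time
#' (gamma = 2^(-3/2) converts the apparent N&B brightness carried by the
#' species into a peak count rate).  Particles keep moving during the scan,
#' including during the retrace.
#'
#' @param trajectories output of [simulate_particles()]; must cover the full
#'   scan duration.
#' @param psf a `psf_model`.
#' @param config a `scan_config`.
#' @param background_rate background counts per dwell per pixel.
#' @param channels `"green"`, `"red"`, or `"both"`.
#' @return An object of class `raster_series`: `counts` is a
#'   frames x rows x cols integer array (or a list of two such arrays for two
#'   channels), plus the config, psf and ground-truth metadata.
#' @export
render_raster_series <- function(trajectories, psf, config,
                                 background_rate = 0.1,
                                 channels = c("green", "both", "red")) {
  channels <- match.arg(channels)
  stopifnot(inherits(trajectories, "particle_trajectories"),
            inherits(psf, "psf_model"), inherits(config, "scan_config"),
            background_rate >= 0)
  if (psf$w0 < config$pixel_size / 10)
    warning("PSF waist below pixel_size/10: the PSF is undersampled",
            call. = FALSE)
  n <- config$image_size
  scan_dur <- config$frame_count * frame_time(config)
  if (trajectories$total_time < scan_dur - 1e-9)
    stop("trajectory duration (", signif(trajectories$total_time, 4),
         " s) is shorter than the scan (", signif(scan_dur, 4), " s)",
         call. = FALSE)
  rate_for <- function(eps) {
    # per-particle interpolation slack: how far a particle can stray within
    # one trajectory step (3 sigma)
    slack <- 3 * sqrt(2 * trajectories$D * trajectories$dt)
    render_scan_cpp(trajectories$positions, trajectories$dt,
                    config$frame_count, n, n,
                    x0 = 0, y0 = 0, px = config$pixel_size,
                    dwell_s = config$pixel_dwell * 1e-6,
                    line_s = config$line_time * 1e-3,
                    frame_s = frame_time(config),
                    w0 = psf$w0, wz = psf$wz,
                    eps_peak = eps / psf_gamma(), slack = slack,
                    z_focus = 0)
  }
  draw <- function(rate) {
    counts <- stats::rpois(length(rate), rate + background_rate)
    array(as.integer(counts), dim = dim(rate))
  }
  counts <- switch(channels,
    green = draw(rate_for(trajectories$eps_green)),
    red = draw(rate_for(trajectories$eps_red)),
    both = list(green = draw(rate_for(trajectories$eps_green)),
                red = draw(rate_for(trajectories$eps_red))))
  structure(list(counts = counts,
                 channels = if (channels == "both") 2L else 1L,
                 channel_names = if (channels == "both") c("green", "red")
                                 else channels,
                 config = config, psf = psf,
                 background_rate = background_rate,
                 ground_truth = list(species = trajectories$species,
                                     geometry = trajectories$geometry)),
            class = "raster_series")
}

#' Build a raster series directly from a counts array
#'
#' Wraps an existing frames x rows x cols photon-count array (for example
#' loaded from disk, or constructed analytically in a test) as a
#' `raster_series`.
#' @param counts integer array frames x rows x cols, or list of two for two
#'   channels.
#' @param config a `scan_config`; frame count is taken from the array.
#' @param psf optional `psf_model`.
#' @export
raster_series <- function(counts, config, psf = NULL) {
  first <- if (is.list(counts)) counts[[1]] else counts
  stopifnot(length(dim(first)) == 3)
  if (any(first < 0)) stop("counts must be nonnegative", call. = FALSE)
  config$frame_count <- dim(first)[1]
  config$image_size <- dim(first)[2]
  structure(list(counts = counts,
                 channels = if (is.list(counts)) length(counts) else 1L,
                 channel_names = if (is.list(counts)) names(counts) else "green",
                 config = config, psf = psf, background_rate = NA_real_,
                 ground_truth = NULL),
            class = "raster_series")
}

#' @export
print.raster_series <- function(x, ...) {
  d <- dim(if (is.list(x$counts)) x$counts[[1]] else x$counts)
  cat("raster_series:", d[1], "frames of", d[2], "x", d[3], "px,",
      x$channels, "channel(s)\n")
  invisible(x)
}

#' Render a line-scan series (pCF acquisition) from trajectories
#'
#' The same photon model as [render_raster_series()] applied to a fixed line
#' of `line_length` pixels scanned `n_lines` times, one line per
#' `line_time`.  Small reference raster images are rendered before and after
#' the series for drift checking; both carry a wall-marker channel (a bright
#' ridge at each wall position, emulating a cell-wall stain) used by
#' [locate_wall()].
#'
#' @inheritParams render_raster_series
#' @param wall_column expected wall pixel (validated to lie inside the line);
#'   `NA` to skip the check when the geometry has no walls.
#' @param drift lateral shift (um, along x) applied to the second reference
#'   image; nonzero values emulate sample movement during acquisition.
#' @return An object of class `line_scan_series` with `counts`
#'   (n_lines x line_length integer matrix, or list of two), the reference
#'   images, config and ground truth.
#' @export
render_line_series <- function(trajectories, psf, config,
                               wall_column = NA, background_rate = 0.1,
                               channels = c("green", "both", "red"),
                               drift = 0) {
  channels <- match.arg(channels)
  stopifnot(inherits(trajectories, "particle_trajectories"),
            inherits(config, "scan_config"))
  nx <- config$line_length
  walls <- trajectories$geometry$walls
  if (!is.na(wall_column)) {
    if (wall_column < 2 || wall_column > nx - 2)
      stop("line must span the wall interior: wall_column must lie in [2, ",
           nx - 2, "]", call. = FALSE)
  } else if (nrow(walls)) {
    wc <- round(walls$position[1] / config$pixel_size)
    if (wc < 2 || wc > nx - 2)
      stop("line must span the wall interior", call. = FALSE)
  }
  scan_dur <- config$n_lines * config$line_time * 1e-3
  if (trajectories$total_time < scan_dur - 1e-9)
    stop("trajectory duration is shorter than the line series", call. = FALSE)
  slack <- 3 * sqrt(2 * trajectories$D * trajectories$dt)
  rate_for <- function(eps) {
    render_scan_cpp(trajectories$positions, trajectories$dt,
                    config$n_lines, 1L, nx,
                    x0 = 0, y0 = 0, px = config$pixel_size,
                    dwell_s = config$pixel_dwell * 1e-6,
                    line_s = config$line_time * 1e-3,
                    frame_s = config$line_time * 1e-3,
                    w0 = psf$w0, wz = psf$wz,
                    eps_peak = eps / psf_gamma(), slack = slack,
                    z_focus = 0)
  }
  draw <- function(rate) {
    m <- matrix(as.integer(stats::rpois(length(rate),
                                        rate + background_rate)),
                nrow = config$n_lines, ncol = nx)
    m
  }
  counts <- switch(channels,
    green = draw(rate_for(trajectories$eps_green)),
    red = draw(rate_for(trajectories$eps_red)),
    both = list(green = draw(rate_for(trajectories$eps_green)),
                red = draw(rate_for(trajectories$eps_red))))
  ref_before <- .render_reference(trajectories, psf, config, shift = 0)
  ref_after <- .render_reference(trajectories, psf, config, shift = drift)
  structure(list(counts = counts,
                 channels = if (channels == "both") 2L else 1L,
                 config = config, psf = psf,
                 background_rate = background_rate,
                 reference_before = ref_before, reference_after = ref_after,
                 ground_truth = list(species = trajectories$species,
                                     geometry = trajectories$geometry)),
            class = "line_scan_series")
}

#' Line-scan series from a counts matrix
#' @param counts integer matrix n_lines x line_length.
#' @param config a `scan_config`.
#' @export
line_scan_series <- function(counts, config) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  config$n_lines <- nrow(counts)
  config$line_length <- ncol(counts)
  structure(list(counts = counts, channels = 1L, config = config,
                 psf = NULL, background_rate = NA_real_,
                 reference_before = NULL, reference_after = NULL,
                 ground_truth = NULL),
            class = "line_scan_series")
}

#' @export
print.line_scan_series <- function(x, ...) {
  cts <- if (is.list(x$counts)) x$counts[[1]] else x$counts
  cat("line_scan_series:", nrow(cts), "lines x", ncol(cts), "px,",
      x$channels, "channel(s)\n")
  invisible(x)
}

# Reference image around the scanned line: mean fluorescence (time-averaged
# over a short dummy acquisition) plus a wall-marker channel with a Gaussian
# ridge at each wall x-position.  `shift` displaces the field along x (um).
.render_reference <- function(trajectories, psf, config, shift = 0,
                              n_rows = 16L) {
  nx <- config$line_length
  px <- config$pixel_size
  xs <- (seq_len(nx) - 1) * px + shift
  walls <- trajectories$geometry$walls
  marker <- rep(0.2, nx)   # faint background in the marker channel
  if (nrow(walls)) {
    # faces closer than 1 um belong to one wall (finite wall thickness);
    # the stain ridge covers the whole wall
    pos <- sort(walls$position)
    cluster <- cumsum(c(1, diff(pos) > 1))
    for (cl in unique(cluster)) {
      span <- range(pos[cluster == cl])
      sg <- diff(span) / 2 + px / 1.5
      marker <- marker + 10 * exp(-(xs - mean(span))^2 / (2 * sg^2))
    }
  }
  fluor <- numeric(nx)
  pos0 <- trajectories$positions[1, , , drop = FALSE]
  eps <- trajectories$eps_green / psf_gamma()
  for (p in seq_along(eps)) {
    if (eps[p] <= 0) next
    dx <- xs - pos0[1, p, 1]
    fluor <- fluor + eps[p] * exp(-2 * (dx^2 + pos0[1, p, 2]^2) / psf$w0^2 -
                                    2 * pos0[1, p, 3]^2 / psf$wz^2)
  }
  list(fluorescence = matrix(rep(fluor, each = n_rows), n_rows, nx),
       wall_marker = matrix(rep(marker, each = n_rows), n_rows, nx),
       shift_um = shift)
}

#' Estimate drift between the two reference images of a line series
#'
#' Cross-correlates the column profiles of the before/after reference images
#' and returns the displacement (in pixels) of the correlation maximum, with
#' a flag raised when it exceeds `max_shift`.
#' @param lines a `line_scan_series` with reference images.
#' @param max_shift tolerated shift in pixels.
#' @return list with `shift_px` and logical `drift_flag`.
#' @export
check_drift <- function(lines, max_shift = 1) {
  rb <- lines$reference_before; ra <- lines$reference_after
  if (is.null(rb) || is.null(ra))
    stop("line series carries no reference images", call. = FALSE)
  a <- colMeans(rb$fluorescence) + colMeans(rb$wall_marker)
  b <- colMeans(ra$fluorescence) + colMeans(ra$wall_marker)
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  shifts <- -(n %/% 2):(n %/% 2)
  cc <- vapply(shifts, function(s) {
    ia <- seq_len(n); ib <- ia + s
    ok <- ib >= 1 & ib <= n
    if (sum(ok) < 4) return(-Inf)
    sum(a[ia[ok]] * b[ib[ok]]) / sum(ok)
  }, numeric(1))
  best <- shifts[which.max(cc)]
  list(shift_px = best, drift_flag = abs(best) > max_shift)
}
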