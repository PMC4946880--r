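# Shared setup for the streaming generator: initial positions and per-
# particle brightness from a species list.
.species_setup <- function(species, geometry) {
  if (inherits(species, "species_spec")) species <- list(species)
  counts <- vapply(species, function(s) s$count, integer(1))
  np <- sum(counts)
  if (np == 0) stop("no particles to simulate", call. = FALSE)
  start <- matrix(0, np, 3)
  D <- eps_g <- eps_r <- numeric(np)
  at <- 0L
  for (s in species) {
    if (s$count == 0) next
    idx <- at + seq_len(s$count)
    rg <- s$region
    xr <- if (!is.null(rg$x)) rg$x else geometry$xlim
    yr <- if (!is.null(rg$y)) rg$y else geometry$ylim
    zr <- if (!is.null(rg$z)) rg$z else geometry$zlim
    start[idx, 1] <- stats::runif(s$count, xr[1], xr[2])
    start[idx, 2] <- stats::runif(s$count, yr[1], yr[2])
    start[idx, 3] <- stats::runif(s$count, zr[1], zr[2])
    D[idx] <- s$diffusion_coefficient
    eps_g[idx] <- s$brightness_per_unit * s$n_fluorophores_green
    eps_r[idx] <- s$brightness_red_per_unit * s$n_fluorophores_red
    at <- at + s$count
  }
  list(species = species, start = start, D = D, eps_g = eps_g,
       eps_r = eps_r)
}

# substeps per active line so that the stepping resolution is about an
# eighth of the beam transit time w0^2/(4D) of the fastest species
.auto_nsub <- function(active_s, w0, Dmax) {
  if (Dmax <= 0) return(1L)
  tau_c <- w0^2 / (4 * Dmax)
  max(2L, min(256L, as.integer(ceiling(active_s / (tau_c / 8)))))
}

#' One-step synthetic raster series generator
#'
#' Streams Brownian dynamics and photon rendering together (exact Gaussian
#' steps at sub-line resolution, nothing stored per time point), producing
#' the same photon model as [simulate_particles()] followed by
#' [render_raster_series()] but at arbitrary time resolution with constant
#' memory.  Preferred for fast-diffusing species.
#'
#' @inheritParams render_raster_series
#' @param species `species_spec` or list of them.
#' @param geometry optional `geometry_spec`; defaults to
#'   [default_geometry()] for the config.
#' @param nsub substeps per active line (`"auto"` targets an eighth of the
#'   fastest beam transit time).
#' @return a `raster_series`.
#' @export
synthesize_raster <- function(species, psf, config, geometry = NULL,
                              background_rate = 0.1,
                              channels = c("green", "both", "red"),
                              nsub = "auto") {
  channels <- match.arg(channels)
  if (is.null(geometry)) geometry <- default_geometry(config, psf, "raster")
  su <- .species_setup(species, geometry)
  n <- config$image_size
  if (identical(nsub, "auto"))
    nsub <- .auto_nsub(n * config$pixel_dwell * 1e-6, psf$w0, max(su$D))
  wm <- as.matrix(geometry$walls[, c("position", "p_f", "p_r"),
                                 drop = FALSE])
  storage.mode(wm) <- "double"
  dom <- c(geometry$xlim, geometry$ylim, geometry$zlim)
  eps <- switch(channels, green = cbind(su$eps_g), red = cbind(su$eps_r),
                both = cbind(su$eps_g, su$eps_r))
  rates <- stream_render_cpp(su$start, su$D, eps / psf_gamma(), dom, wm,
                             config$frame_count, n, n, 0, 0,
                             config$pixel_size, config$pixel_dwell * 1e-6,
                             config$line_time * 1e-3, psf$w0, psf$wz, 0,
                             as.integer(nsub),
                             as.integer(isTRUE(geometry$periodic_x)))
  draw <- function(rate) array(as.integer(
    stats::rpois(length(rate), rate + background_rate)), dim = dim(rate))
  counts <- if (channels == "both") {
    list(green = draw(rates[[1]]), red = draw(rates[[2]]))
  } else {
    draw(rates[[1]])
  }
  structure(list(counts = counts,
                 channels = if (channels == "both") 2L else 1L,
                 channel_names = if (channels == "both") c("green", "red")
                                 else channels,
                 config = config, psf = psf,
                 background_rate = background_rate,
                 ground_truth = list(species = su$species,
                                     geometry = geometry)),
            class = "raster_series")
}

#' One-step synthetic line-scan series generator
#'
#' Streaming counterpart of [simulate_particles()] +
#' [render_line_series()]: generates the n_lines x line_length photon-count
#' carpet with constant memory, including semi-permeable wall dynamics, plus
#' the reference images used for wall localisation and drift checks.
#'
#' @inheritParams synthesize_raster
#' @inheritParams render_line_series
#' @return a `line_scan_series`.
#' @export
synthesize_lines <- function(species, psf, config, geometry = NULL,
                             background_rate = 0.1,
                             channels = c("green", "both", "red"),
                             nsub = "auto", drift = 0) {
  channels <- match.arg(channels)
  if (is.null(geometry)) geometry <- default_geometry(config, psf, "line")
  su <- .species_setup(species, geometry)
  nx <- config$line_length
  walls <- geometry$walls
  if (nrow(walls)) {
    wc <- round(walls$position[1] / config$pixel_size)
    if (wc < 2 || wc > nx - 2)
      stop("line must span the wall interior", call. = FALSE)
  }
  if (identical(nsub, "auto"))
    nsub <- .auto_nsub(nx * config$pixel_dwell * 1e-6, psf$w0, max(su$D))
  wm <- as.matrix(walls[, c("position", "p_f", "p_r"), drop = FALSE])
  storage.mode(wm) <- "double"
  dom <- c(geometry$xlim, geometry$ylim, geometry$zlim)
  eps <- switch(channels, green = cbind(su$eps_g), red = cbind(su$eps_r),
                both = cbind(su$eps_g, su$eps_r))
  rates <- stream_render_cpp(su$start, su$D, eps / psf_gamma(), dom, wm,
                             config$n_lines, 1L, nx, 0, 0,
                             config$pixel_size, config$pixel_dwell * 1e-6,
                             config$line_time * 1e-3, psf$w0, psf$wz, 0,
                             as.integer(nsub),
                             as.integer(isTRUE(geometry$periodic_x)))
  draw <- function(rate) matrix(as.integer(
    stats::rpois(length(rate), rate + background_rate)),
    nrow = config$n_lines, ncol = nx)
  counts <- if (channels == "both") {
    list(green = draw(rates[[1]]), red = draw(rates[[2]]))
  } else {
    draw(rates[[1]])
  }
  fake_traj <- list(positions = array(su$start,
                                      dim = c(1, nrow(su$start), 3)),
                    eps_green = su$eps_g, geometry = geometry)
  ref_before <- .render_reference(fake_traj, psf, config, shift = 0)
  ref_after <- .render_reference(fake_traj, psf, config, shift = drift)
  structure(list(counts = counts,
                 channels = if (channels == "both") 2L else 1L,
                 config = config, psf = psf,
                 background_rate = background_rate,
                 reference_before = ref_before, reference_after = ref_after,
                 ground_truth = list(species = su$species,
                                     geometry = geometry)),
            class = "line_scan_series")
}
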