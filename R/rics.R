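#' Moving-average subtraction of the immobile fraction
#'
#' Removes stationary and slow-moving structure from a raster time series
#' before image correlation: for each retained frame the pixelwise mean of
#' the `window` surrounding frames (the `window/2` preceding and following
#' frames) is subtracted and the series grand mean is re-added so the
#' correlation normalisation stays defined.  Frames within `window/2` of
#' either end are dropped.
#'
#' @param series a `raster_series` (single channel).
#' @param window moving-average window in frames (even; default 10).
#' @return a `raster_series` with `frame_count - window` frames.
#' @examples
#' cfg <- scan_config(frame_count = 20, image_size = 8)
#' x <- raster_series(array(5L, dim = c(20, 8, 8)), cfg)
#' dim(subtract_moving_average(x)$counts)  # 10 frames retained
#' @export
subtract_moving_average <- function(series, window = 10L) {
  stopifnot(inherits(series, "raster_series"))
  counts <- series$counts
  if (is.list(counts))
    stop("apply subtract_moving_average per channel", call. = FALSE)
  nf <- dim(counts)[1]
  window <- as.integer(window)
  if (window >= nf)
    stop("window (", window, ") must be smaller than the frame count (",
         nf, ")", call. = FALSE)
  h <- window %/% 2L
  keep <- (h + 1L):(nf - h)
  grand <- mean(counts)
  # cumulative sum over frames for O(frames) windowed means per pixel
  d <- dim(counts)
  flat <- matrix(as.numeric(counts), nrow = nf)
  cs <- rbind(0, apply(flat, 2, cumsum))
  out <- matrix(0, length(keep), ncol(flat))
  for (k in seq_along(keep)) {
    i <- keep[k]
    # mean of the h preceding and h following frames (frame i excluded is a
    # matter of convention; the surrounding-window mean includes i so that a
    # temporally constant series maps to exactly the grand mean)
    win_sum <- cs[i + h + 1L, ] - cs[i - h, ]
    out[k, ] <- flat[i, ] - win_sum / (window + 1L) + grand
  }
  res <- series
  res$counts <- array(out, dim = c(length(keep), d[2], d[3]))
  res$config$frame_count <- length(keep)
  res$moving_average_window <- window
  res
}

#' Spatial autocorrelation surface of a raster series
#'
#' Computes the RICS autocorrelation
#' `G_S(xi, psi) = <dI(x, y) dI(x + xi, y + psi)> / <I>^2`
#' averaged over frames, where `dI` is the deviation of a frame from its
#' mean.  The correlation is evaluated by FFT with zero padding (no
#' wraparound); the per-lag products are normalised by the number of
#' overlapping pixel pairs.  Lags are reported to +/- size/4.
#'
#' @param series a `raster_series`, already moving-average filtered.
#' @param roi optional region of interest `c(x0, y0, size)` (0-based origin).
#' @return object of class `acf_surface`: matrix `values` indexed
#'   `[psi, xi]`, lag vectors `xi` and `psi` (pixels), amplitude `G0`, and
#'   the acquisition metadata needed for fitting.
#' @export
compute_acf <- function(series, roi = NULL) {
  stopifnot(inherits(series, "raster_series"))
  counts <- series$counts
  if (is.list(counts)) stop("compute_acf is per channel", call. = FALSE)
  d <- dim(counts)
  if (!is.null(roi)) {
    stopifnot(length(roi) == 3)
    x0 <- roi[1]; y0 <- roi[2]; sz <- roi[3]
    if (x0 < 0 || y0 < 0 || x0 + sz > d[3] || y0 + sz > d[2])
      stop("ROI extends outside the image", call. = FALSE)
    counts <- counts[, y0 + seq_len(sz), x0 + seq_len(sz), drop = FALSE]
    d <- dim(counts)
  }
  nf <- d[1]; ny <- d[2]; nx <- d[3]
  max_xi <- nx %/% 4L; max_psi <- ny %/% 4L
  py <- 2L * ny; pxn <- 2L * nx
  # overlap counts per lag (same for every frame)
  novl <- outer(ny - abs(-(max_psi):max_psi), nx - abs(-(max_xi):max_xi))
  acc <- matrix(0, 2 * max_psi + 1, 2 * max_xi + 1)
  for (f in seq_len(nf)) {
    fr <- matrix(counts[f, , ], ny, nx)
    mu <- mean(fr)
    if (mu == 0) next
    dI <- fr - mu
    pad <- matrix(0, py, pxn)
    pad[seq_len(ny), seq_len(nx)] <- dI
    ft <- stats::fft(pad)
    corr <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / (py * pxn)
    # corr[1 + ((psi) mod py), 1 + ((xi) mod pxn)] = sum products at lag
    idx_psi <- ((-(max_psi):max_psi) %% py) + 1L
    idx_xi <- ((-(max_xi):max_xi) %% pxn) + 1L
    acc <- acc + corr[idx_psi, idx_xi] / novl / mu^2
  }
  values <- acc / nf
  structure(list(values = values,
                 xi = -(max_xi):max_xi, psi = -(max_psi):max_psi,
                 G0 = values[max_psi + 1L, max_xi + 1L],
                 config = series$config, n_frames = nf),
            class = "acf_surface")
}

#' @export
print.acf_surface <- function(x, ...) {
  cat("acf_surface:", length(x$psi), "x", length(x$xi),
      "lags, G(0,0) =", signif(x$G0, 4), "\n")
  invisible(x)
}

#' @export
plot.acf_surface <- function(x, ...) {
  graphics::image(x$xi, x$psi, t(x$values),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = expression(xi ~ "(px)"),
                  ylab = expression(psi ~ "(px)"), ...)
}

# One-component 3D Gaussian RICS model: G_S = S * G with
#   tau(xi, psi) = |tau_p * xi + tau_l * psi|   (signed scan-time lag)
#   G = G0 * (1 + 4 D tau / w0^2)^-1 * (1 + 4 D tau / wz^2)^-1/2
#   S = exp(-((xi dx)^2 + (psi dx)^2) / (w0^2 + 4 D tau))
.rics_model <- function(xi, psi, D, G0, w0, wz, dx, tau_p, tau_l) {
  tau <- abs(tau_p * xi + tau_l * psi)
  g <- G0 / ((1 + 4 * D * tau / w0^2) * sqrt(1 + 4 * D * tau / wz^2))
  s <- exp(-((xi * dx)^2 + (psi * dx)^2) / (w0^2 + 4 * D * tau))
  s * g
}

#' Fit the 3D Gaussian diffusion model to a RICS autocorrelation surface
#'
#' Bounded nonlinear least squares of `G_S = S * G` over the diffusion
#' coefficient D and amplitude G0, on lags up to +/- size/4 with the zero
#' lag excluded (shot-noise spike).  D is optimised on a log scale within
#' `[1e-3, 1e3]` um^2/s with multi-starts at `D0 * c(0.1, 1, 10)`; ties are
#' broken by lowest sum of squared residuals.  The quality-control flag
#' passes when the surface maximum is at least three times the largest
#' absolute residual.
#'
#' @param acf an `acf_surface`.
#' @param psf a `psf_model`.
#' @param config a `scan_config` (defaults to the one stored in `acf`).
#' @param init optional `c(D0, G00)` starting values.
#' @return object of class `diffusion_fit` with elements `D` (um^2/s), `G0`,
#'   `residuals` (surface), `qc_pass`, `sse`, `converged`, `n_frames_used`.
#' @export
fit_diffusion <- function(acf, psf, config = acf$config, init = NULL) {
  stopifnot(inherits(acf, "acf_surface"), inherits(psf, "psf_model"))
  stopifnot(all(is.finite(acf$values)))
  dx <- config$pixel_size
  tau_p <- config$pixel_dwell * 1e-6
  tau_l <- config$line_time * 1e-3
  grid <- expand.grid(xi = acf$xi, psi = acf$psi)
  vals <- as.vector(t(acf$values))   # values[psi, xi] -> xi fastest
  keep <- !(grid$xi == 0 & grid$psi == 0)
  g <- grid[keep, ]; y <- vals[keep]
  D0 <- if (is.null(init)) 5 else init[1]
  G00 <- if (is.null(init)) max(acf$values[acf$psi == 0, ][-(length(acf$xi) %/% 2 + 1)], 0.01)
         else init[2]
  lowerD <- 1e-3; upperD <- 1e3
  best <- NULL
  for (mult in c(0.1, 1, 10)) {
    Ds <- min(max(D0 * mult, lowerD), upperD)
    fit <- try(minpack.lm::nls.lm(
      par = c(logD = log(Ds), G0 = G00, off = 0),
      lower = c(log(lowerD), 0, -Inf), upper = c(log(upperD), Inf, Inf),
      fn = function(p) {
        .rics_model(g$xi, g$psi, exp(p[1]), p[2], psf$w0, psf$wz,
                    dx, tau_p, tau_l) + p[3] - y
      },
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(D = NA_real_, G0 = NA_real_, residuals = NULL,
                          qc_pass = FALSE, sse = NA_real_, converged = FALSE,
                          n_frames_used = acf$n_frames),
                     class = "diffusion_fit"))
  }
  p <- best$fit$par
  D <- exp(p[[1]]); G0 <- p[[2]]; off <- p[[3]]
  pred <- matrix(off + .rics_model(grid$xi, grid$psi, D, G0, psf$w0,
                                   psf$wz, dx, tau_p, tau_l),
                 nrow = length(acf$psi), ncol = length(acf$xi), byrow = TRUE)
  resid <- acf$values - pred
  # the zero-lag pixel is excluded from both the fit and the QC rule
  resid_qc <- resid
  resid_qc[acf$psi == 0, acf$xi == 0] <- 0
  qc <- max(acf$values) >= 3 * max(abs(resid_qc))
  structure(list(D = D, G0 = G0, offset = off, fitted = pred,
                 residuals = resid,
                 qc_pass = qc, sse = best$sse,
                 converged = best$fit$info %in% 1:4,
                 n_frames_used = acf$n_frames),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("diffusion_fit: D =", signif(x$D, 4), "um^2/s, G0 =",
      signif(x$G0, 4), "| qc_pass =", x$qc_pass, "\n")
  invisible(x)
}

#' Calibrate the PSF beam waist from a solution scan
#'
#' Fits the RICS autocorrelation of a spatially homogeneous solution series
#' with the diffusion coefficient clamped to a known value (free EGFP in
#' water, 78 um^2/s), solving for the lateral waist w0; wz is tied to w0 by
#' the fixed axial ratio.
#'
#' @param solution_series a `raster_series` of a homogeneous dye/protein
#'   solution (no geometry).
#' @param fixed_D known diffusion coefficient in um^2/s (default 78).
#' @param axial_ratio wz/w0 (default 3).
#' @param window moving-average window passed to
#'   [subtract_moving_average()].
#' @return a `psf_model` with attributes `G0` and `sse`.
#' @export
calibrate_psf <- function(solution_series, fixed_D = 78, axial_ratio = 3,
                          window = 10L) {
  if (fixed_D <= 0) stop("fixed_D must be positive", call. = FALSE)
  flt <- subtract_moving_average(solution_series, window = window)
  acf <- compute_acf(flt)
  config <- acf$config
  dx <- config$pixel_size
  tau_p <- config$pixel_dwell * 1e-6
  tau_l <- config$line_time * 1e-3
  grid <- expand.grid(xi = acf$xi, psi = acf$psi)
  vals <- as.vector(t(acf$values))
  keep <- !(grid$xi == 0 & grid$psi == 0)
  g <- grid[keep, ]; y <- vals[keep]
  lower_w <- dx / 2; upper_w <- 50 * dx
  G00 <- max(max(acf$values[acf$psi == 0, ]), 0.01)
  fit <- minpack.lm::nls.lm(
    par = c(w0 = 5 * dx, G0 = G00, off = 0),
    lower = c(lower_w, 0, -Inf), upper = c(upper_w, Inf, Inf),
    fn = function(p) {
      .rics_model(g$xi, g$psi, fixed_D, p[2], p[1], axial_ratio * p[1],
                  dx, tau_p, tau_l) + p[3] - y
    },
    control = minpack.lm::nls.lm.control(maxiter = 200))
  w0 <- fit$par[[1]]
  if (w0 <= lower_w * 1.001 || w0 >= upper_w * 0.999)
    stop("PSF unidentifiable at these settings (waist fit at bound)",
         call. = FALSE)
  out <- psf_model(w0 = w0, axial_ratio = axial_ratio)
  attr(out, "G0") <- fit$par[[2]]
  attr(out, "sse") <- sum(fit$fvec^2)
  out
}
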