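# Per-pixel moment statistics over frames with 10-frame moving-average
# detrending.  The detrended variance of white noise is biased by
# (1 - 1/(window+1)) because the inclusive surrounding-window mean contains
# the frame itself; the estimate is divided by that factor so that pure shot
# noise keeps variance = mean.
.pixel_moments <- function(counts, detrend_window = 10L) {
  nf <- dim(counts)[1]
  flat <- matrix(as.numeric(counts), nrow = nf)
  dd <- .detrended_dev(counts, detrend_window)
  list(mean = colMeans(flat),
       var = colSums(dd$dev^2) / nrow(dd$dev) / dd$bias,
       frames_used = nrow(dd$dev))
}

.boxcar2d <- function(m, k) {
  if (k <= 1) return(m)
  pad <- k %/% 2
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, ny, nx)
  cs <- matrix(0, ny + 1, nx + 1)
  m0 <- m; m0[is.na(m0)] <- 0
  w <- !is.na(m)
  cs[-1, -1] <- apply(apply(m0, 2, cumsum), 1, cumsum) |> t()
  cw <- matrix(0, ny + 1, nx + 1)
  cw[-1, -1] <- apply(apply(w * 1, 2, cumsum), 1, cumsum) |> t()
  for (r in seq_len(ny)) {
    r1 <- max(1, r - pad); r2 <- min(ny, r + pad)
    for (c in seq_len(nx)) {
      c1 <- max(1, c - pad); c2 <- min(nx, c + pad)
      s <- cs[r2 + 1, c2 + 1] - cs[r1, c2 + 1] - cs[r2 + 1, c1] + cs[r1, c1]
      n <- cw[r2 + 1, c2 + 1] - cw[r1, c2 + 1] - cw[r2 + 1, c1] + cw[r1, c1]
      out[r, c] <- if (n > 0) s / n else NA_real_
    }
  }
  out
}

#' Per-pixel number and brightness map
#'
#' Moment (N&B) analysis of a raster time series: for every pixel the mean
#' `<k>` and population variance `sigma^2` of the photon counts over frames
#' give the apparent brightness `B = s_factor * sigma^2 / <k>` and apparent
#' number `N = <k>^2 / sigma^2`.  A 10-frame moving-average detrend removes
#' the immobile fraction before the variance is formed (bias-corrected so
#' pure shot noise stays at B = 1 when `s_factor = 1`).  Pixels with zero
#' mean are masked (`NA`), not treated as 0/0.
#'
#' @param series a `raster_series` (single channel) or a frames x rows x
#'   cols counts array.
#' @param s_factor detector scaling placing the background at B = 1 (see
#'   [calibrate_sfactor()]).
#' @param detrend_window frames for the immobile-fraction detrend (0 to
#'   disable).
#' @param smooth_px boxcar side length applied to the B and N maps (1 to
#'   disable).  Per-pixel B at 50-100 frames has relative noise
#'   sqrt(2/K); light spatial smoothing is required before cursor
#'   classification.
#' @return object of class `brightness_map` with matrices `mean`, `var`,
#'   `B`, `N`, the frames used `K`, and the s-factor applied.
#' @export
brightness_map <- function(series, s_factor = 1, detrend_window = 10L,
                           smooth_px = 5L) {
  counts <- if (inherits(series, "raster_series")) series$counts else series
  if (is.list(counts)) stop("brightness_map is per channel", call. = FALSE)
  stopifnot(length(dim(counts)) == 3)
  d <- dim(counts)
  if (d[1] < 30)
    warning("fewer than 30 frames: variance estimates are unstable",
            call. = FALSE)
  mom <- .pixel_moments(counts, detrend_window)
  mean_m <- matrix(mom$mean, d[2], d[3])
  var_m <- matrix(mom$var, d[2], d[3])
  B <- s_factor * var_m / mean_m
  N <- mean_m^2 / var_m
  B[mean_m == 0] <- NA_real_
  N[mean_m == 0 | var_m == 0] <- NA_real_
  B <- .boxcar2d(B, smooth_px)
  N <- .boxcar2d(N, smooth_px)
  structure(list(mean = mean_m, var = var_m, B = B, N = N,
                 K = mom$frames_used, s_factor = s_factor,
                 detrend_window = detrend_window, smooth_px = smooth_px),
            class = "brightness_map")
}

#' @export
print.brightness_map <- function(x, ...) {
  cat("brightness_map:", nrow(x$B), "x", ncol(x$B), "px, K =", x$K,
      "| median B =", signif(stats::median(x$B, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' Calibrate the detector S-factor on a background-only series
#'
#' The S-factor standardises the detector output so that the
#' background/immobile population is centred at B = 1:
#' `s_factor = 1 / median(raw B over background pixels)`.
#'
#' @param background_series a `raster_series` of a region without sample
#'   (shot noise and autofluorescence only), or a counts array.
#' @param mask optional logical matrix selecting background pixels; default
#'   all.
#' @param min_pixels minimum background pixels required (default 500).
#' @inheritParams brightness_map
#' @return the scalar s-factor.
#' @export
calibrate_sfactor <- function(background_series, mask = NULL,
                              detrend_window = 10L, min_pixels = 500L) {
  bm <- brightness_map(background_series, s_factor = 1,
                       detrend_window = detrend_window, smooth_px = 1L)
  vals <- bm$B
  if (!is.null(mask)) vals <- vals[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) < min_pixels)
    stop("background region too small: ", length(vals), " pixels (need ",
         min_pixels, ")", call. = FALSE)
  1 / stats::median(vals)
}

#' Measure monomer brightness and cursor size from a monomeric line
#'
#' The monomeric brightness epsilon is the mode of `B - 1` over fluorescent
#' pixels of a series known to contain only monomers; the cursor size is the
#' span covering the central 95% of the monomer B distribution.  A clearly
#' bimodal B distribution (the sample is not monomeric) is an error.
#'
#' @param map a `brightness_map` of the monomeric sample (S-factor already
#'   applied).
#' @param min_intensity pixels with `<k>` at or below this are background
#'   and are excluded.
#' @return object of class `cursor_spec`: `epsilon`, `cursor_size`,
#'   `s_factor`.
#' @export
measure_monomer <- function(map, min_intensity = 0.2) {
  stopifnot(inherits(map, "brightness_map"))
  sel <- is.finite(map$B) & map$mean > min_intensity & map$B > 1
  b <- map$B[sel]
  if (length(b) < 50)
    stop("too few fluorescent pixels to measure the monomer", call. = FALSE)
  dens <- stats::density(b, n = 512)
  # bimodality guard: a secondary density peak comparable to the main one
  peaks <- which(diff(sign(diff(dens$y))) == -2) + 1
  if (length(peaks) > 1) {
    py <- sort(dens$y[peaks], decreasing = TRUE)
    px <- dens$x[peaks[order(dens$y[peaks], decreasing = TRUE)]]
    if (py[2] > 0.5 * py[1] && abs(px[2] - px[1]) > 2 * stats::bw.nrd0(b))
      stop("sample not monomeric: brightness distribution is bimodal",
           call. = FALSE)
  }
  eps <- dens$x[which.max(dens$y)] - 1
  qs <- stats::quantile(b, c(0.025, 0.975), names = FALSE)
  structure(list(epsilon = eps, cursor_size = diff(qs),
                 s_factor = map$s_factor, n_pixels = length(b)),
            class = "cursor_spec")
}

#' Cursor specification for oligomer classification
#' @param epsilon monomeric brightness (counts/dwell/molecule; the
#'   above-background brightness B - 1 of a monomer).
#' @param cursor_size full width of a cursor window on the B axis.
#' @param s_factor detector S-factor the brightness maps were computed with.
#' @export
cursor_spec <- function(epsilon, cursor_size = NULL, s_factor = 1) {
  stopifnot(epsilon > 0)
  if (is.null(cursor_size)) cursor_size <- epsilon
  structure(list(epsilon = epsilon, cursor_size = cursor_size,
                 s_factor = s_factor), class = "cursor_spec")
}

#' @export
print.cursor_spec <- function(x, ...) {
  cat("cursor_spec: epsilon =", signif(x$epsilon, 3), ", cursor size =",
      signif(x$cursor_size, 3), "\n")
  invisible(x)
}

#' Classify pixels into monomer and homodimer populations
#'
#' The monomer cursor is a B window of width `cursor_size` centred at
#' `1 + epsilon`; the homodimer cursor has the same width and is centred at
#' `1 + 2*epsilon` (the above-background brightness doubles while the
#' shot-noise unit does not).  Percentages are computed over classified
#' (monomer + dimer) pixels only.
#'
#' @param map a `brightness_map` (same instrument settings and s-factor as
#'   the cursor calibration).
#' @param cursor a `cursor_spec`.
#' @param min_intensity background-intensity threshold as in
#'   [measure_monomer()].
#' @return list with `pct_monomer`, `pct_dimer`, `n_monomer`, `n_dimer`,
#'   `n_fluorescent`.
#' @export
classify_oligomers <- function(map, cursor, min_intensity = 0.2) {
  stopifnot(inherits(map, "brightness_map"), inherits(cursor, "cursor_spec"))
  eps <- cursor$epsilon; cs <- cursor$cursor_size
  if (cs >= 2 * eps)
    stop("overlapping cursors: cursor_size must be below 2*epsilon (",
         "monomer brightness must exceed ", signif(cs / 2, 3), ")",
         call. = FALSE)
  sel <- is.finite(map$B) & map$mean > min_intensity
  b <- map$B[sel]
  mono <- b >= 1 + eps - cs / 2 & b <= 1 + eps + cs / 2
  dim2 <- b >= 1 + 2 * eps - cs / 2 & b <= 1 + 2 * eps + cs / 2
  n_m <- sum(mono); n_d <- sum(dim2)
  tot <- n_m + n_d
  list(pct_monomer = if (tot) 100 * n_m / tot else NA_real_,
       pct_dimer = if (tot) 100 * n_d / tot else NA_real_,
       n_monomer = n_m, n_dimer = n_d, n_fluorescent = length(b))
}

#' Two-colour cross number-and-brightness map
#'
#' Computes the per-pixel cross-variance of the detrended green and red
#' channels, `sigma_cc^2 = sum_i (G_i - <G>)(R_i - <R>) / K`, and from it
#' the cross-brightness `B_cc = sigma_cc^2 / (<G> <R>)` and cross-number
#' `N_cc = <G> <R> / sigma_cc^2`.  Independent channels give `B_cc ~ 0`;
#' co-moving (complexed) species give positive `B_cc`.  Significance is
#' assessed against a temporal-shuffle null: pixels are flagged where
#' `B_cc` exceeds the chosen quantile of the map recomputed with one
#' channel's frames permuted.
#'
#' @param green,red `raster_series` or frames x rows x cols count arrays,
#'   pixel-registered and frame-synchronous.
#' @param detrend_window frames for immobile-fraction detrending.
#' @param smooth_px boxcar smoothing of the output maps.
#' @param null_level quantile of the shuffled-null B_cc defining
#'   significance (default 0.95).
#' @return object of class `cross_map` with matrices `sigma_cc2`, `B_cc`,
#'   `N_cc`, `significant`, channel means `mean_g`, `mean_r`, and the null
#'   threshold.
#' @export
cross_brightness <- function(green, red, detrend_window = 10L,
                             smooth_px = 3L, null_level = 0.95) {
  gc_ <- if (inherits(green, "raster_series")) green$counts else green
  rc_ <- if (inherits(red, "raster_series")) red$counts else red
  if (is.list(gc_) || is.list(rc_))
    stop("pass single-channel series", call. = FALSE)
  if (!identical(dim(gc_), dim(rc_)))
    stop("green and red series must have identical shape and frame count",
         call. = FALSE)
  d <- dim(gc_)
  nf <- d[1]
  cross_of <- function(ga, ra) {
    gm <- .detrended_dev(ga, detrend_window)
    rm_ <- .detrended_dev(ra, detrend_window)
    colSums(gm$dev * rm_$dev) / nrow(gm$dev) / gm$bias
  }
  scc <- cross_of(gc_, rc_)
  momg <- .pixel_moments(gc_, detrend_window)
  momr <- .pixel_moments(rc_, detrend_window)
  mean_g <- matrix(momg$mean, d[2], d[3])
  mean_r <- matrix(momr$mean, d[2], d[3])
  scc_m <- matrix(scc, d[2], d[3])
  denom <- mean_g * mean_r
  Bcc <- scc_m / denom
  Bcc[denom <= 0] <- NA_real_
  Ncc <- denom / scc_m
  Ncc[denom <= 0 | scc_m == 0] <- NA_real_
  Bcc <- .boxcar2d(Bcc, smooth_px)
  # temporal-shuffle null for the significance threshold
  perm <- sample.int(nf)
  scc_null <- cross_of(gc_, rc_[perm, , , drop = FALSE])
  Bcc_null <- matrix(scc_null, d[2], d[3]) / denom
  Bcc_null[denom <= 0] <- NA_real_
  Bcc_null <- .boxcar2d(Bcc_null, smooth_px)
  thr <- stats::quantile(Bcc_null, null_level, na.rm = TRUE, names = FALSE)
  structure(list(sigma_cc2 = scc_m, B_cc = Bcc, N_cc = Ncc,
                 mean_g = mean_g, mean_r = mean_r,
                 significant = is.finite(Bcc) & Bcc > thr,
                 null_threshold = thr, K = momg$frames_used),
            class = "cross_map")
}

# shared detrended deviations used by the variance and cross-variance paths
.detrended_dev <- function(counts, detrend_window) {
  nf <- dim(counts)[1]
  flat <- matrix(as.numeric(counts), nrow = nf)
  if (detrend_window > 0 && detrend_window < nf) {
    h <- detrend_window %/% 2L
    keep <- (h + 1L):(nf - h)
    cs <- rbind(0, apply(flat, 2, cumsum))
    dev <- matrix(0, length(keep), ncol(flat))
    for (k in seq_along(keep)) {
      i <- keep[k]
      win_mean <- (cs[i + h + 1L, ] - cs[i - h, ]) / (detrend_window + 1L)
      dev[k, ] <- flat[i, ] - win_mean
    }
    list(dev = dev, bias = 1 - 1 / (detrend_window + 1L))
  } else {
    list(dev = sweep(flat, 2, colMeans(flat)), bias = 1)
  }
}

#' @export
print.cross_map <- function(x, ...) {
  cat("cross_map:", nrow(x$B_cc), "x", ncol(x$B_cc), "px,",
      sum(x$significant, na.rm = TRUE), "significant pixels\n")
  invisible(x)
}

#' Stoichiometry of a two-colour complex from cross-N&B maps
#'
#' Among pixels with significant positive cross-brightness, each pixel is
#' classified on the (green B, red B) plane: green monomer cursor with red
#' monomer cursor means a 1:1 complex; green homodimer cursor with red
#' monomer cursor means a 2:1 complex.  Percentages are over complexed
#' (classified) pixels; the classifier reports no (., 2) class when no
#' red-homodimer complexes rise above significance.
#'
#' @param cross a `cross_map`.
#' @param map_green,map_red `brightness_map`s of the two channels.
#' @param cursor_green,cursor_red `cursor_spec`s for the two fluorophores.
#' @param min_intensity intensity floor for fluorescent pixels.
#' @return object of class `stoichiometry_result`: `fraction_11`,
#'   `fraction_21` (percent of complexed pixels), `n_11`, `n_21`,
#'   `n_complexed`, and a `histogram` data.frame (stoichiometry classes and
#'   counts).  `n_complexed = 0` yields a warning, not an error.
#' @export
complex_stoichiometry <- function(cross, map_green, map_red, cursor_green,
                                  cursor_red, min_intensity = 0.2) {
  stopifnot(inherits(cross, "cross_map"))
  in_cursor <- function(b, center, cs) {
    is.finite(b) & b >= center - cs / 2 & b <= center + cs / 2
  }
  eg <- cursor_green$epsilon; cg <- cursor_green$cursor_size
  er <- cursor_red$epsilon; cr <- cursor_red$cursor_size
  sel <- cross$significant & cross$mean_g > min_intensity &
    cross$mean_r > min_intensity
  bg <- map_green$B; br <- map_red$B
  g_mono <- in_cursor(bg, 1 + eg, cg)
  g_dim <- in_cursor(bg, 1 + 2 * eg, cg)
  r_mono <- in_cursor(br, 1 + er, cr)
  r_dim <- in_cursor(br, 1 + 2 * er, cr)
  n11 <- sum(sel & g_mono & r_mono, na.rm = TRUE)
  n21 <- sum(sel & g_dim & r_mono, na.rm = TRUE)
  n12 <- sum(sel & g_mono & r_dim, na.rm = TRUE)
  n22 <- sum(sel & g_dim & r_dim, na.rm = TRUE)
  tot <- n11 + n21
  if (tot == 0)
    warning("no cross-correlated pixels classified", call. = FALSE)
  hist <- data.frame(green_units = c(1L, 2L, 1L, 2L),
                     red_units = c(1L, 1L, 2L, 2L),
                     n_pixels = c(n11, n21, n12, n22))
  structure(list(fraction_11 = if (tot) 100 * n11 / tot else NA_real_,
                 fraction_21 = if (tot) 100 * n21 / tot else NA_real_,
                 n_11 = n11, n_21 = n21, n_complexed = tot,
                 histogram = hist),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat("stoichiometry:", round(x$fraction_11, 1), "% 1:1,",
      round(x$fraction_21, 1), "% 2:1 (n =", x$n_complexed, "pixels)\n")
  invisible(x)
}
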