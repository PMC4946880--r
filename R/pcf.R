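#' Period-average a line-scan carpet and trim photobleached tails
#'
#' Produces a display view (block means over consecutive groups of `period`
#' lines, the conventional way to make carpet trends visible) and an analysis
#' series with any photobleached tail removed.  Bleaching is detected as a
#' monotone decline of the per-period mean intensity beyond
#' `bleach_threshold`; when detected, periods after the intensity first drops
#' below `1 - bleach_threshold` of the initial level are trimmed.
#'
#' @param lines a `line_scan_series` (single channel).
#' @param period lines per display block (default 800).
#' @param bleach_threshold fractional intensity loss that flags bleaching
#'   (default 0.2).
#' @param min_lines minimum analysis length; trimming below this is an error.
#' @return list with `display` (periods x line_length matrix), `analysis`
#'   (trimmed `line_scan_series`), `bleach_flag`, `trimmed_lines`.
#' @export
prepare_carpet <- function(lines, period = 800L, bleach_threshold = 0.2,
                           min_lines = 1e4) {
  stopifnot(inherits(lines, "line_scan_series"))
  counts <- lines$counts
  if (is.list(counts)) stop("prepare_carpet is per channel", call. = FALSE)
  n <- nrow(counts)
  if (n < 2L * period)
    stop("need at least 2 periods of lines", call. = FALSE)
  nper <- n %/% period
  used <- nper * period
  blocks <- matrix(0, nper, ncol(counts))
  per_mean <- numeric(nper)
  for (b in seq_len(nper)) {
    idx <- ((b - 1L) * period + 1L):(b * period)
    blocks[b, ] <- colMeans(counts[idx, , drop = FALSE])
    per_mean[b] <- mean(counts[idx, ])
  }
  rel <- per_mean / per_mean[1]
  decline <- 1 - rel[nper]
  monotone <- nper >= 4 &&
    suppressWarnings(stats::cor(seq_len(nper), per_mean,
                                method = "spearman")) < -0.6
  bleach <- isTRUE(decline > bleach_threshold && monotone)
  trim_after <- n
  if (bleach) {
    bad <- which(rel < 1 - bleach_threshold)
    trim_after <- (min(bad) - 1L) * period
    if (trim_after < min_lines)
      stop("bleach trim would leave fewer than ", min_lines, " lines",
           call. = FALSE)
  }
  analysis <- lines
  analysis$counts <- counts[seq_len(trim_after), , drop = FALSE]
  analysis$config$n_lines <- trim_after
  list(display = blocks, analysis = analysis, bleach_flag = bleach,
       trimmed_lines = n - trim_after)
}

# Logarithmic delay grid in lines: `per_decade` points per decade from 1 to
# n_lines/10 line times.
.log_delays <- function(n_lines, per_decade = 32L) {
  top <- max(2, n_lines %/% 10L)
  tau <- unique(round(10^(seq(0, log10(top), by = 1 / per_decade))))
  tau[tau >= 1 & tau <= top]
}

# Temporal correlation of two equal-length series at the given integer
# delays: G(tau) = <F(t) F(t+tau)> / (<F> <F>) - 1, full-series means.
.pair_corr_series <- function(f1, f2, delays) {
  n <- length(f1)
  m1 <- mean(f1); m2 <- mean(f2)
  if (m1 == 0 || m2 == 0) return(rep(NA_real_, length(delays)))
  # FFT cross-correlation: sum_t f1(t) f2(t+tau) for tau >= 0
  np <- stats::nextn(2L * n, 2)
  a <- c(f1, rep(0, np - n))
  b <- c(f2, rep(0, np - n))
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b),
                      inverse = TRUE)) / np
  g <- cc[delays + 1L] / (n - delays) / (m1 * m2) - 1
  g
}

#' Per-column temporal autocorrelation carpet
#'
#' Computes the temporal autocorrelation of each column of a line scan after
#' moving-average detrending (window `window` lines, removing immobile and
#' slowly varying structure), on a logarithmic delay grid.
#'
#' @param lines a `line_scan_series`.
#' @param window detrending moving-average window in lines (default 200).
#' @param per_decade log-grid density (default 32 points per decade).
#' @return object of class `pcf_carpet` with `values` (delays x columns),
#'   `delays` (lines), `delay_s` (seconds), `delta_r = 0`.
#' @export
column_autocorrelation <- function(lines, window = 200L, per_decade = 32L) {
  stopifnot(inherits(lines, "line_scan_series"))
  counts <- lines$counts
  if (is.list(counts)) counts <- counts[[1]]
  n <- nrow(counts)
  if (window >= n)
    stop("window must be smaller than the number of lines", call. = FALSE)
  delays <- .log_delays(n, per_decade)
  vals <- matrix(NA_real_, length(delays), ncol(counts))
  for (j in seq_len(ncol(counts))) {
    f <- as.numeric(counts[, j])
    mu <- mean(f)
    trend <- stats::filter(f, rep(1 / window, window), sides = 2)
    trend[is.na(trend)] <- mu
    det <- f - as.numeric(trend) + mu
    vals[, j] <- .pair_corr_series(det, det, delays)
  }
  structure(list(values = vals, delays = delays,
                 delay_s = delays * lines$config$line_time * 1e-3,
                 delta_r = 0L, direction = "forward",
                 columns = seq_len(ncol(counts)) - 1L,
                 config = lines$config, period_averaged = FALSE,
                 color_scale = c(high = "red", low = "blue", none = "black")),
            class = "pcf_carpet")
}

#' Locate the cell-wall column along the scanned line
#'
#' The wall column is the position of the wall-marker channel's intensity
#' maximum along the line of the reference image (for synthetic data the
#' marker ridge is rendered at the ground-truth wall; for real data this is
#' the cell-wall stain channel).
#'
#' @param reference either the reference-image list produced by
#'   [render_line_series()] (with a `wall_marker` element) or a numeric
#'   matrix/vector of marker intensities along the line.
#' @param min_contrast required ratio of the maximum to the background
#'   (median) marker level.
#' @return 0-based wall column index.
#' @export
locate_wall <- function(reference, min_contrast = 2) {
  prof <- if (is.list(reference) && !is.null(reference$wall_marker)) {
    colMeans(reference$wall_marker)
  } else if (is.matrix(reference)) {
    colMeans(reference)
  } else {
    as.numeric(reference)
  }
  bg <- stats::median(prof)
  if (bg <= 0) bg <- mean(prof)
  if (max(prof) < min_contrast * bg)
    stop("wall not localizable: marker contrast below ", min_contrast,
         "x background", call. = FALSE)
  which.max(prof) - 1L
}

#' Pair correlation carpet at pixel separation delta_r
#'
#' For each column c the fluorescence series at c is correlated against the
#' series at `c + delta_r` (forward) or `c - delta_r` (reverse) at
#' log-spaced delays:
#' `G(tau, dr) = <F(t, 0) F(t + tau, dr)> / (<F(t, 0)> <F(t, dr)>) - 1`.
#' Columns whose partner falls outside the line are reported as missing
#' (`NA`), not zero.
#'
#' @param lines a `line_scan_series` (analysis series from
#'   [prepare_carpet()], or raw).
#' @param delta_r pixel separation (5, 7 or 9 in standard runs).
#' @param direction `"forward"` (left to right) or `"reverse"`.
#' @param per_decade log-grid density.
#' @param columns optional 0-based source columns to compute (default all);
#'   other columns are reported missing.
#' @return a `pcf_carpet`; `values[tau, c]` is the correlation of source
#'   column c (0-based) with its partner.
#' @export
pair_correlation <- function(lines, delta_r,
                             direction = c("forward", "reverse"),
                             per_decade = 32L, columns = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(lines, "line_scan_series"))
  counts <- lines$counts
  if (is.list(counts)) counts <- counts[[1]]
  nx <- ncol(counts)
  if (delta_r >= nx)
    stop("delta_r must be smaller than the line length", call. = FALSE)
  if (delta_r == 0) return(column_autocorrelation(lines,
                                                  per_decade = per_decade))
  n <- nrow(counts)
  delays <- .log_delays(n, per_decade)
  vals <- matrix(NA_real_, length(delays), nx)
  step <- if (direction == "forward") delta_r else -delta_r
  wanted <- if (is.null(columns)) seq_len(nx) else
    intersect(as.integer(columns) + 1L, seq_len(nx))
  for (c0 in wanted) {
    c1 <- c0 + step
    if (c1 < 1 || c1 > nx) next   # partner exits the line: stays missing
    vals[, c0] <- .pair_corr_series(as.numeric(counts[, c0]),
                                    as.numeric(counts[, c1]), delays)
  }
  structure(list(values = vals, delays = delays,
                 delay_s = delays * lines$config$line_time * 1e-3,
                 delta_r = as.integer(delta_r), direction = direction,
                 columns = seq_len(nx) - 1L, config = lines$config,
                 period_averaged = FALSE,
                 color_scale = c(high = "red", low = "blue", none = "black")),
            class = "pcf_carpet")
}

#' @export
print.pcf_carpet <- function(x, ...) {
  cat("pcf_carpet: delta_r =", x$delta_r, "(", x$direction, "),",
      nrow(x$values), "delays x", ncol(x$values), "columns\n")
  invisible(x)
}

#' @export
plot.pcf_carpet <- function(x, ...) {
  graphics::image(x$columns, log10(x$delays), t(x$values),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "line position (px)",
                  ylab = expression(log[10] ~ tau ~ "(lines)"), ...)
}

#' Automated arch call on a pCF carpet
#'
#' Molecules crossing the barrier produce a delayed positive correlation
#' band (the "arch") in column pairs spanning the wall.  This automated
#' surrogate for the visual call computes, over the wall-spanning column
#' pairs closest to symmetric about the wall, the maximum over a delay
#' window of the period-smoothed pair correlation (columns are averaged
#' over blocks of `period` lines and detrended before correlating), and
#' compares it with the `level` quantile of a block-shuffled null in which
#' time blocks of the partner columns are permuted -- destroying
#' cross-column delay structure while preserving each column's own
#' autocorrelation.
#'
#' @param carpet a `pcf_carpet` from [pair_correlation()] (supplies the
#'   pixel separation and direction).
#' @param wall_column 0-based wall column (see [locate_wall()]).
#' @param lines the `line_scan_series` the carpet was computed from.
#' @param n_perm permutations for the null (default 200).
#' @param period period-averaging span in lines for the smoothed statistic
#'   (default 8).
#' @param block shuffle block length in periods (default 32).
#' @param tau_range delay window in lines (default `c(32, 320)`); the lower
#'   edge excludes the instantaneous cross-talk of a particle seen by both
#'   columns at once, the upper edge bounds the crossing delay considered.
#' @param level null quantile (default 0.95).
#' @param max_pairs wall-spanning column pairs averaged (default 4).
#' @param smooth delay-axis smoothing window in delay bins.
#' @param detrend_periods running-mean window (in periods) removed from each
#'   column before correlating, to suppress slow drifts.
#' @return 1 if an arch is detected, else 0; attributes `stat`, `threshold`,
#'   `p_value`.
#' @export
detect_arch <- function(carpet, wall_column, lines, n_perm = 200L,
                        period = 8L, block = 32L, tau_range = c(32, 320),
                        level = 0.95, max_pairs = 4L, smooth = 3L,
                        detrend_periods = 501L) {
  stopifnot(inherits(carpet, "pcf_carpet"),
            inherits(lines, "line_scan_series"))
  counts <- lines$counts
  if (is.list(counts)) counts <- counts[[1]]
  nx <- ncol(counts); n <- nrow(counts)
  dr <- carpet$delta_r
  if (dr <= 0) stop("arch detection needs delta_r > 0", call. = FALSE)
  step <- if (carpet$direction == "forward") dr else -dr
  # source columns whose pair spans the wall (wall between c0 and c0+step)
  src <- which(vapply(seq_len(nx), function(c0) {
    c1 <- c0 + step
    if (c1 < 1 || c1 > nx) return(FALSE)
    lo <- min(c0, c1) - 1L; hi <- max(c0, c1) - 1L   # 0-based
    lo <= wall_column && wall_column < hi
  }, logical(1)))
  if (!length(src))
    stop("no column pair spans the wall at this delta_r", call. = FALSE)
  if (all(is.na(carpet$values[, src])))
    stop("carpet is missing at the wall", call. = FALSE)
  # keep the pairs most symmetric about the wall so the two columns sit on
  # opposite sides at comparable distances
  mid <- (src - 1) + step / 2   # 0-based midpoint of each pair
  src <- src[order(abs(mid - wall_column))][seq_len(min(max_pairs,
                                                        length(src)))]
  # period-average (the period-smoothed view of the carpet) and detrend
  decimate <- function(v) {
    m <- (length(v) %/% period) * period
    colMeans(matrix(v[seq_len(m)], period))
  }
  detrend <- function(v) {
    w <- min(detrend_periods, 2L * (length(v) %/% 4L) + 1L)
    tr <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
    tr[is.na(tr)] <- mean(v)
    v - tr + mean(v)
  }
  A <- lapply(src, function(c0) detrend(decimate(counts[, c0])))
  B <- lapply(src, function(c0) detrend(decimate(counts[, c0 + step])))
  nb <- length(A[[1]]) %/% block
  if (nb < 8)
    stop("series too short for the block-shuffle null", call. = FALSE)
  L <- nb * block
  A <- lapply(A, function(v) v[seq_len(L)])
  B <- lapply(B, function(v) v[seq_len(L)])
  d_lo <- max(1L, as.integer(floor(tau_range[1] / period)))
  d_hi <- max(d_lo + smooth, as.integer(ceiling(tau_range[2] / period)))
  d_hi <- min(d_hi, L %/% 4L)
  dgrid <- d_lo:d_hi
  mu_a <- vapply(A, mean, numeric(1))
  mu_b <- vapply(B, mean, numeric(1))
  if (any(mu_a == 0) || any(mu_b == 0))
    stop("carpet is missing at the wall", call. = FALSE)
  # shifted copies of each source column so that a profile is one
  # matrix-vector product per pair: Ash[t, j] = A[t - d_j]
  Ash <- lapply(A, function(a) {
    m <- matrix(0, L, length(dgrid))
    for (j in seq_along(dgrid)) {
      d <- dgrid[j]
      m[(1 + d):L, j] <- a[seq_len(L - d)]
    }
    m
  })
  profile_of <- function(Bl) {
    prof <- rowMeans(vapply(seq_along(A), function(i) {
      sums <- as.numeric(crossprod(Ash[[i]], Bl[[i]]))
      sums / (L - dgrid) / (mu_a[i] * mu_b[i]) - 1
    }, numeric(length(dgrid))))
    if (smooth > 1)
      prof <- as.numeric(stats::filter(prof, rep(1 / smooth, smooth),
                                       sides = 2))
    max(prof, na.rm = TRUE)
  }
  s_obs <- profile_of(B)
  null_stats <- vapply(seq_len(n_perm), function(k) {
    perm <- sample.int(nb)
    idx <- as.vector(outer(seq_len(block), (perm - 1L) * block, `+`))
    profile_of(lapply(B, function(v) v[idx]))
  }, numeric(1))
  thr <- stats::quantile(null_stats, level, names = FALSE, na.rm = TRUE)
  # permutation test with the add-one estimator (exact level <= 1 - level)
  p_val <- (1 + sum(null_stats >= s_obs)) / (1 + n_perm)
  call <- as.integer(is.finite(s_obs) && p_val <= 1 - level)
  attr(call, "stat") <- s_obs
  attr(call, "threshold") <- thr
  attr(call, "p_value") <- p_val
  call
}

#' Movement Index from binary arch calls
#'
#' Each biological replicate contributes the mean of its binary arch calls
#' over the pixel distances used (5, 7 and 9 by default); the Movement Index
#' is the mean over replicates, with its standard error.
#'
#' @param calls a list with one numeric vector of 0/1 calls per replicate,
#'   or a single vector (treated as one replicate).
#' @return object of class `movement_index`: `MI`, `sem`, `n`,
#'   `replicate_means`.
#' @examples
#' movement_index(list(c(1, 0, 1), c(1, 1, 1)))
#' @export
movement_index <- function(calls) {
  if (is.numeric(calls)) calls <- list(calls)
  if (!length(calls)) stop("no replicates supplied", call. = FALSE)
  if (any(!vapply(calls, length, integer(1))))
    stop("every replicate needs at least one distance call", call. = FALSE)
  reps <- vapply(calls, function(x) {
    stopifnot(all(x %in% c(0, 1)))
    mean(x)
  }, numeric(1))
  n <- length(reps)
  structure(list(MI = mean(reps),
                 sem = if (n > 1) stats::sd(reps) / sqrt(n) else NA_real_,
                 n = n, replicate_means = reps),
            class = "movement_index")
}

#' @export
print.movement_index <- function(x, ...) {
  cat("Movement Index:", round(x$MI, 3), "+/-",
      ifelse(is.na(x$sem), "NA", round(x$sem, 3)), "(n =", x$n, ")\n")
  invisible(x)
}
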