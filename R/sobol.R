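#' Default Sobol parameter set and bounds for the SHR/SCR model
#'
#' The 15 varied quantities are the independent rate and equilibrium
#' constants of the wild-type model: k1, a1, a2, d1..d6, L, k3, K1D, K2D,
#' k4, k5 (the logistic shape constants k and C0 are held fixed).  Bounds
#' default to 0.25x to 4x each default value, sampled log-uniformly; a2,
#' whose wild-type default is zero, is sampled over a1's bounds since it is
#' the symmetric transport rate.
#'
#' @param params a `model_params` supplying the central values.
#' @return data.frame with columns `parameter`, `lower`, `upper`, `log`.
#' @export
default_sobol_bounds <- function(params = default_model_params()) {
  nm <- c("k1", "a1", "a2", "d1", "d2", "d3", "d4", "d5", "d6",
          "L", "k3", "K1D", "K2D", "k4", "k5")
  ctr <- unlist(params[nm])
  ctr[["a2"]] <- ctr[["a1"]]
  data.frame(parameter = nm, lower = ctr / 4, upper = ctr * 4,
             log = TRUE, row.names = NULL)
}

#' Radial Sobol sampling design
#'
#' Two independent N x p matrices A and B of parameter draws, plus the
#' radial matrices C_i (A with column i replaced by column i of B), as used
#' by the total-effect estimator.
#'
#' @param bounds data.frame as from [default_sobol_bounds()]: columns
#'   `parameter`, `lower`, `upper` and optionally `log` (log-uniform
#'   sampling).
#' @param N rows per matrix (default 1000).
#' @return object of class `sobol_design` with `A`, `B` (matrices) and
#'   `C` (list of p matrices).
#' @export
generate_design <- function(bounds, N = 1000L) {
  stopifnot(is.data.frame(bounds),
            all(c("parameter", "lower", "upper") %in% names(bounds)))
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)) ||
      any(bounds$lower >= bounds$upper))
    stop("degenerate bounds: need finite lower < upper for every parameter",
         call. = FALSE)
  p <- nrow(bounds)
  lg <- if ("log" %in% names(bounds)) bounds$log else rep(FALSE, p)
  draw <- function() {
    m <- matrix(0, N, p, dimnames = list(NULL, bounds$parameter))
    for (j in seq_len(p)) {
      if (lg[j]) {
        m[, j] <- exp(stats::runif(N, log(bounds$lower[j]),
                                   log(bounds$upper[j])))
      } else {
        m[, j] <- stats::runif(N, bounds$lower[j], bounds$upper[j])
      }
    }
    m
  }
  A <- draw(); B <- draw()
  C <- lapply(seq_len(p), function(i) { m <- A; m[, i] <- B[, i]; m })
  names(C) <- bounds$parameter
  structure(list(A = A, B = B, C = C, N = N, bounds = bounds),
            class = "sobol_design")
}

#' Evaluate the model outcomes over a design matrix
#'
#' Each row of the matrix is one parameter draw; the model is integrated
#' over `[0, t_end]` and each of the six state variables is reduced to a
#' scalar outcome by trapezoidal time integration on the solver grid.
#' Rows where the solver fails are returned as `NA` (the estimator excludes
#' them pairwise); a failure rate above 5% raises a warning.
#'
#' @param mat design matrix (columns named by parameter).
#' @param base_params `model_params` supplying the non-varied parameters.
#' @param t_end integration horizon in hours.
#' @param dt output grid spacing.
#' @param init initial state passed to [simulate_model()].
#' @return N x 6 matrix of integrated outcomes (one column per state).
#' @export
evaluate_outcomes <- function(mat, base_params = default_model_params(),
                              t_end = 24, dt = 0.25, init = NULL) {
  vars <- c("Sv", "Se", "S2e", "C", "SC", "S2C")
  out <- matrix(NA_real_, nrow(mat), 6, dimnames = list(NULL, vars))
  fails <- 0L
  for (r in seq_len(nrow(mat))) {
    p <- base_params
    for (nm in colnames(mat)) p[[nm]] <- mat[r, nm]
    traj <- try(simulate_model(p, init = init, t_end = t_end, dt = dt,
                               mode = "wildtype"), silent = TRUE)
    if (inherits(traj, "try-error")) { fails <- fails + 1L; next }
    tt <- traj$time
    for (v in seq_along(vars)) {
      y <- traj$states[, vars[v]]
      out[r, v] <- sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    }
  }
  if (fails > 0.05 * nrow(mat))
    warning(fails, " of ", nrow(mat), " design rows failed to integrate",
            call. = FALSE)
  out
}

#' Sobol total-effect indices (Jansen estimator)
#'
#' For each parameter i and each outcome column,
#' `S_Ti = (1/(2N)) sum_j (f(A)_j - f(C_i)_j)^2 / V(Y)`,
#' with `V(Y)` the sample variance of `f(A)`.  Rows that failed in either
#' matrix are excluded pairwise.
#'
#' @param fA N x m outcome matrix for design matrix A.
#' @param fC list of N x m outcome matrices, one per parameter (f(C_i)).
#' @return object of class `sobol_result`: matrix `S_T` (parameters x
#'   outcomes), `V` (outcome variances), `n_used`.
#' @export
total_effect_indices <- function(fA, fC) {
  stopifnot(is.list(fC))
  p <- length(fC)
  m <- ncol(fA)
  S <- matrix(NA_real_, p, m,
              dimnames = list(names(fC), colnames(fA)))
  n_used <- matrix(0L, p, m, dimnames = dimnames(S))
  V <- apply(fA, 2, stats::var, na.rm = TRUE)
  if (any(!is.finite(V)) || any(V == 0))
    stop("outcome variance is zero or undefined: indices undefined",
         call. = FALSE)
  for (i in seq_len(p)) {
    stopifnot(nrow(fC[[i]]) == nrow(fA))
    for (v in seq_len(m)) {
      ok <- is.finite(fA[, v]) & is.finite(fC[[i]][, v])
      n <- sum(ok)
      n_used[i, v] <- n
      if (n < 2) next
      S[i, v] <- sum((fA[ok, v] - fC[[i]][ok, v])^2) / (2 * n) /
        stats::var(fA[ok, v])
    }
  }
  structure(list(S_T = S, V = V, n_used = n_used), class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  print(round(x$S_T, 3))
  invisible(x)
}

#' Run one full Sobol replicate on the SHR/SCR model
#'
#' Convenience wrapper: design generation, model evaluation over A and all
#' C_i, and the total-effect estimator.
#'
#' @inheritParams generate_design
#' @inheritParams evaluate_outcomes
#' @return a `sobol_result`.
#' @export
sobol_replicate <- function(bounds = default_sobol_bounds(), N = 1000L,
                            base_params = default_model_params(),
                            t_end = 24, dt = 0.25) {
  des <- generate_design(bounds, N)
  fA <- evaluate_outcomes(des$A, base_params, t_end, dt)
  fC <- lapply(des$C, evaluate_outcomes, base_params = base_params,
               t_end = t_end, dt = dt)
  total_effect_indices(fA, fC)
}

#' Normalise Sobol replicates and flag influential parameters
#'
#' Within each replicate and outcome the 15 indices are z-normalised (mean
#' 0, variance 1 across parameters) and then averaged over replicates.  A
#' parameter is flagged influential for an outcome when all-pairs rank
#' comparisons (Wilcoxon rank-sum statistics with a Steel-Dwass style
#' studentised-range adjustment) show it significantly greater than at
#' least three quarters of the other parameters at level `alpha`.
#'
#' @param results list of `sobol_result` replicates (>= 2 for testing; a
#'   single replicate returns the normalisation only).
#' @param alpha significance level (default 0.10).
#' @return list with `normalized` (parameters x outcomes mean z-scores),
#'   `influential` (logical matrix), `n_replicates`.
#' @export
normalize_and_rank <- function(results, alpha = 0.10) {
  if (inherits(results, "sobol_result")) results <- list(results)
  R <- length(results)
  S0 <- results[[1]]$S_T
  p <- nrow(S0); m <- ncol(S0)
  z <- array(NA_real_, c(R, p, m))
  for (r in seq_len(R)) {
    s <- results[[r]]$S_T
    for (v in seq_len(m)) {
      mu <- mean(s[, v], na.rm = TRUE)
      sd_ <- stats::sd(s[, v], na.rm = TRUE)
      z[r, , v] <- if (isTRUE(sd_ > 0)) (s[, v] - mu) / sd_ else 0
    }
  }
  normalized <- apply(z, c(2, 3), mean, na.rm = TRUE)
  dimnames(normalized) <- dimnames(S0)
  influential <- matrix(FALSE, p, m, dimnames = dimnames(S0))
  if (R >= 2) {
    crit <- stats::qtukey(1 - alpha, nmeans = p, df = Inf) / sqrt(2)
    for (v in seq_len(m)) {
      zs <- z[, , v, drop = FALSE][, , 1]
      if (R == 1) zs <- matrix(zs, nrow = 1)
      for (i in seq_len(p)) {
        wins <- 0L
        for (j in seq_len(p)) {
          if (i == j) next
          xi <- zs[, i]; xj <- zs[, j]
          # large-sample rank-sum z statistic, one-sided (i greater)
          rk <- rank(c(xi, xj))
          W <- sum(rk[seq_len(R)])
          mu_w <- R * (2 * R + 1) / 2
          sd_w <- sqrt(R * R * (2 * R + 1) / 12)
          zstat <- (W - mu_w) / sd_w
          if (zstat > crit) wins <- wins + 1L
        }
        influential[i, v] <- wins >= ceiling(0.75 * (p - 1))
      }
    }
  }
  list(normalized = normalized, influential = influential,
       n_replicates = R)
}
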