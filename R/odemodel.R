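#' Logistic homodimerisation rate k2(C)
#'
#' The SHR homodimer formation rate switches on once the SCR concentration
#' passes the critical value `C0`, rising at steepness `k` to the maximum
#' `L`: `k2(C) = L / (1 + exp(-k (C - C0)))`.
#'
#' @param C SCR concentration (arbitrary units); vectorised.
#' @param L maximum rate.
#' @param k logistic steepness.
#' @param C0 SCR threshold.
#' @return rate values in (0, L).
#' @examples
#' k2_of_C(360, L = 0.5, k = 0.1, C0 = 360)  # L/2 at the midpoint
#' @export
k2_of_C <- function(C, L = 0.5, k = 0.1, C0 = 360) {
  stopifnot(L > 0, k > 0, C0 > 0)
  L / (1 + exp(-k * (C - C0)))
}

#' Intercellular transport rate from a diffusion coefficient
#'
#' The compartmental transport rate is the measured diffusion coefficient
#' divided by the area of the source cell, `a = D / A`, converted to the
#' model's time unit.
#'
#' @param D diffusion coefficient in um^2/s.
#' @param A cell area in um^2.
#' @param time_unit `"per_hr"` (model default) or `"per_s"`.
#' @return transport rate in the requested unit.
#' @examples
#' transport_rate(2.45, 100, "per_s")  # 0.0245 s^-1
#' @export
transport_rate <- function(D, A, time_unit = c("per_hr", "per_s")) {
  time_unit <- match.arg(time_unit)
  if (A <= 0) stop("cell area must be positive", call. = FALSE)
  if (D < 0) stop("diffusion coefficient must be nonnegative", call. = FALSE)
  a <- D / A
  if (time_unit == "per_hr") a <- a * 3600
  a
}

#' Parameter set for the SHR/SCR compartment model
#'
#' All rates are per hour; concentrations are arbitrary units.  `a1` and
#' `a2` may be given directly or derived from diffusion coefficients and
#' cell areas via `a = D/A` (with `a2 = 0` in the wild type and
#' `a2 = D2/A2` in the SCR-knockdown mode).
#'
#' @param k1 SHR production rate in the vasculature.
#' @param a1 vasculature-to-endodermis transport rate (per hr); derived from
#'   `D1/A1` when missing.
#' @param a2 endodermis-to-vasculature transport rate; 0 in wild type.
#' @param D1,A1 diffusion coefficient (um^2/s) and vascular cell area
#'   (um^2) behind `a1`.
#' @param D2,A2 same for the reverse direction (endodermal cell).
#' @param d1,d2,d3,d4,d5,d6 linear degradation rates of Sv, Se, S2e, C, SC,
#'   S2C.
#' @param L,k,C0 logistic dimerisation parameters (see [k2_of_C()]).
#' @param k3 maximum SCR production rate.
#' @param K1D,K2D Hill dissociation constants of SCR activation.
#' @param k4,k5 association rates of the 1:1 and 2:1 complexes.
#' @return object of class `model_params` (a named list).
#' @export
model_params <- function(k1, a1 = NULL, a2 = 0, D1 = 2.45, A1 = 100,
                         D2 = 2.40, A2 = 150, d1, d2, d3, L = 0.5, k = 0.1,
                         C0 = 360, k3, K1D, K2D, d4, k4, d5, k5, d6) {
  if (is.null(a1)) a1 <- transport_rate(D1, A1)
  p <- list(k1 = k1, a1 = a1, a2 = a2, D1 = D1, A1 = A1, D2 = D2, A2 = A2,
            d1 = d1, d2 = d2, d3 = d3, L = L, k = k, C0 = C0, k3 = k3,
            K1D = K1D, K2D = K2D, d4 = d4, k4 = k4, d5 = d5, k5 = k5,
            d6 = d6)
  rates <- p[setdiff(names(p), c("a2"))]
  if (any(unlist(rates) < 0) || a2 < 0)
    stop("model parameters must be nonnegative", call. = FALSE)
  stopifnot(L > 0, k > 0, C0 > 0)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  v <- unlist(x[setdiff(names(x), "provenance")])
  print(round(v, 5))
  invisible(x)
}

#' Default SHR/SCR model parameters
#'
#' Reads the parameter table shipped with the package
#' (`inst/extdata/shr_scr_parameters.tsv`), which records each value with a
#' provenance flag: `measured` (scanning-FCS measurements: D1, D2),
#' `constraint` (logistic switch built to the SCR-threshold observation) or
#' `estimated` (tuned against the N&B composition data; see
#' [estimate_parameters()]).
#'
#' @param mode `"wildtype"` (a2 = 0) or `"scri"` (a2 = D2/A2).
#' @return a `model_params` with a `provenance` attribute.
#' @export
default_model_params <- function(mode = c("wildtype", "scri")) {
  mode <- match.arg(mode)
  path <- system.file("extdata", "shr_scr_parameters.tsv",
                      package = "scanfcs", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(as.list(tab$value), tab$parameter)
  p <- model_params(k1 = vals$k1, D1 = vals$D1, A1 = vals$A1,
                    D2 = vals$D2, A2 = vals$A2,
                    a2 = if (mode == "scri")
                      transport_rate(vals$D2, vals$A2) else 0,
                    d1 = vals$d1, d2 = vals$d2, d3 = vals$d3,
                    L = vals$L, k = vals$k, C0 = vals$C0, k3 = vals$k3,
                    K1D = vals$K1D, K2D = vals$K2D, d4 = vals$d4,
                    k4 = vals$k4, d5 = vals$d5, k5 = vals$k5, d6 = vals$d6)
  attr(p, "provenance") <- stats::setNames(tab$provenance, tab$parameter)
  p
}

#' Right-hand side of the SHR/SCR ODE system
#'
#' The six coupled equations of the compartment model.  In `wildtype` mode
#' SCR follows its Hill production/degradation balance; in `scri` mode
#' (SCR knockdown) `dC/dt = 0` exactly (SCR is held at its reduced level)
#' and reverse transport `a2` is active.
#'
#' State order: `Sv` (SHR, vasculature), `Se` (SHR monomer, endodermis),
#' `S2e` (SHR homodimer), `C` (SCR), `SC` (1:1 complex), `S2C` (2:1
#' complex).
#'
#' @param state named numeric vector of the six state variables.
#' @param params a `model_params`.
#' @param mode `"wildtype"` or `"scri"`.
#' @return named numeric vector of time derivatives (per hour).
#' @export
shr_scr_rhs <- function(state, params, mode = c("wildtype", "scri")) {
  mode <- match.arg(mode)
  p <- params
  Sv <- state[["Sv"]]; Se <- state[["Se"]]; S2e <- state[["S2e"]]
  C <- state[["C"]]; SC <- state[["SC"]]; S2C <- state[["S2C"]]
  k2 <- k2_of_C(C, p$L, p$k, p$C0)
  dSv <- p$k1 - p$a1 * Sv + p$a2 * Se - p$d1 * Sv
  dSe <- p$a1 * Sv - p$a2 * Se - p$d2 * Se
  dS2e <- k2 * Se^2 - p$d3 * S2e
  dC <- if (mode == "scri") 0 else {
    num <- p$K1D^2 * C + p$K1D * SC + S2C
    den <- p$K1D^2 * p$K2D + p$K1D * p$K2D * Sv + num
    p$k3 * num / den - p$d4 * C
  }
  dSC <- p$k4 * Se * C - p$d5 * SC
  dS2C <- p$k5 * S2e * C - p$d6 * S2C
  c(Sv = dSv, Se = dSe, S2e = dS2e, C = dC, SC = dSC, S2C = dS2C)
}

#' Integrate the SHR/SCR model
#'
#' Stiff-capable integration (`deSolve::lsoda`) at relative tolerance 1e-8.
#' Nonnegativity is preserved by the solver tolerances, never by clipping.
#'
#' @param params a `model_params`.
#' @param init named initial state; defaults to all-zero except a small
#'   basal SCR level `C = 10`.
#' @param t_end end time in hours.
#' @param mode `"wildtype"` or `"scri"`.
#' @param dt output grid spacing in hours.
#' @return object of class `model_trajectory`: `time`, `states` (matrix),
#'   `params`, `mode`.
#' @export
simulate_model <- function(params, init = NULL, t_end = 24, dt = 0.05,
                           mode = c("wildtype", "scri")) {
  mode <- match.arg(mode)
  stopifnot(t_end > 0)
  if (is.null(init))
    init <- c(Sv = 0, Se = 0, S2e = 0, C = 10, SC = 0, S2C = 0)
  if (any(init < 0))
    stop("initial conditions must be nonnegative", call. = FALSE)
  times <- seq(0, t_end, by = dt)
  rhs <- function(t, y, parms) list(shr_scr_rhs(y, parms, mode))
  sol <- deSolve::lsoda(y = init, times = times, func = rhs, parms = params,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed near t = ",
         signif(max(sol[, "time"], na.rm = TRUE), 4), " hr", call. = FALSE)
  states <- unclass(sol)[, -1, drop = FALSE]
  structure(list(time = sol[, "time"], states = states, params = params,
                 mode = mode), class = "model_trajectory")
}

#' @export
print.model_trajectory <- function(x, ...) {
  cat("model_trajectory (", x$mode, "): t in [0, ",
      max(x$time), "] hr\n", sep = "")
  cat("terminal state:\n")
  print(round(x$states[nrow(x$states), ], 4))
  invisible(x)
}

#' @export
plot.model_trajectory <- function(x, ...) {
  graphics::matplot(x$time, x$states, type = "l", lty = 1,
                    xlab = "time (hr)", ylab = "concentration (a.u.)", ...)
  graphics::legend("topleft", legend = colnames(x$states),
                   col = seq_len(ncol(x$states)), lty = 1, bty = "n")
}

#' Steady-state metrics of a model trajectory
#'
#' `steady_state_time` is the earliest time after which every state variable
#' stays within `tol` (relative) of its terminal value; the composition
#' metrics are the entity-wise percentages
#' `homodimer_pct = 100 * S2e / (Se + S2e)` and
#' `complex21_pct = 100 * S2C / (SC + S2C)` at the terminus.
#'
#' @param traj a `model_trajectory`.
#' @param tol relative tolerance defining "steady" (default 0.01).
#' @return list with `steady_state_time` (hr, `NA` with a warning when the
#'   trajectory has not settled), `homodimer_pct`, `complex21_pct`,
#'   `terminal` state vector.
#' @export
steady_state_metrics <- function(traj, tol = 0.01) {
  stopifnot(inherits(traj, "model_trajectory"))
  st <- traj$states
  terminal <- st[nrow(st), ]
  scale <- pmax(abs(terminal), 1e-9)
  # the terminus itself must have stopped moving: relative rate of change
  # per hour below tol for every variable
  rate <- abs(shr_scr_rhs(terminal, traj$params, traj$mode)) / scale
  converged <- all(rate <= tol)
  dev <- sweep(abs(sweep(st, 2, terminal)), 2, scale, "/")
  ok <- apply(dev <= tol, 1, all)
  # earliest time from which the trajectory never leaves the band
  stays <- rev(cumprod(rev(ok))) > 0
  sst <- if (converged && any(stays)) traj$time[which(stays)[1]] else
    NA_real_
  if (is.na(sst))
    warning("trajectory has not reached steady state by t_end",
            call. = FALSE)
  pool_e <- terminal[["Se"]] + terminal[["S2e"]]
  pool_c <- terminal[["SC"]] + terminal[["S2C"]]
  list(steady_state_time = sst,
       homodimer_pct = if (pool_e > 0) 100 * terminal[["S2e"]] / pool_e
                       else NA_real_,
       complex21_pct = if (pool_c > 0) 100 * terminal[["S2C"]] / pool_c
                       else NA_real_,
       terminal = terminal)
}
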