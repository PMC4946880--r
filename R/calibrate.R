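#' Composition targets for model calibration
#'
#' The calibration constrains the wild-type steady state to the N&B-derived
#' composition measurements: the homodimer share of endodermal SHR entities
#' and the 2:1 share of SHR-SCR complexes.
#'
#' @param homodimer_pct target percent of endodermal SHR entities that are
#'   homodimers (default 7.5).
#' @param complex21_pct target percent of complexes with 2:1 stoichiometry
#'   (default 15.2).
#' @param tolerance acceptance tolerance in percentage points (default 0.5).
#' @return object of class `calibration_target`.
#' @export
calibration_target <- function(homodimer_pct = 7.5, complex21_pct = 15.2,
                               tolerance = 0.5) {
  stopifnot(homodimer_pct > 0, homodimer_pct < 100,
            complex21_pct > 0, complex21_pct < 100, tolerance > 0)
  structure(list(homodimer_pct = homodimer_pct,
                 complex21_pct = complex21_pct, tolerance = tolerance),
            class = "calibration_target")
}

# steady-state composition of a parameter set (long integration)
.steady_composition <- function(params, t_end = 120, dt = 0.25) {
  traj <- try(simulate_model(params, t_end = t_end, dt = dt,
                             mode = "wildtype"), silent = TRUE)
  if (inherits(traj, "try-error")) return(NULL)
  suppressWarnings(steady_state_metrics(traj))
}

# objective: worst absolute deviation of the two percentages from target
.calib_objective <- function(params, targets) {
  met <- .steady_composition(params)
  if (is.null(met) || !is.finite(met$homodimer_pct) ||
      !is.finite(met$complex21_pct)) return(list(obj = Inf, metrics = met))
  list(obj = max(abs(met$homodimer_pct - targets$homodimer_pct),
                 abs(met$complex21_pct - targets$complex21_pct)),
       metrics = met)
}

#' One-at-a-time calibration of the SHR/SCR model composition
#'
#' Reproduces the parameter-estimation procedure: starting from the default
#' parameter values, the free parameters (`d2`, `K2D`, `L` by default) are
#' varied one at a time -- cyclic coordinate descent with per-parameter
#' log-grid refinement, at most `max_cycles` cycles -- to minimise the worst
#' absolute deviation of the steady-state homodimer and 2:1-complex
#' percentages from the targets.  `k3` and `d4` are never varied.  During
#' the search the logistic threshold `C0` is re-tied to 60% of the current
#' SCR steady state at the start of every cycle.
#'
#' @param defaults starting `model_params`.
#' @param targets a `calibration_target`.
#' @param free character vector of parameters to vary (must exclude `k3`
#'   and `d4`).
#' @param max_cycles coordinate-descent cycles (default 3).
#' @param grid_span half-width of the log grid in factors of the current
#'   value (default 16: the first sweep spans x1/16 .. x16).
#' @param grid_points points per sweep (default 9).
#' @return object of class `calibration_fit`: `params` (fitted),
#'   `achieved` (homodimer/complex21 percentages), `converged` (within
#'   tolerance), `trace` (data.frame of accepted moves), `defaults`.
#' @export
estimate_parameters <- function(defaults, targets = calibration_target(),
                                free = c("d2", "K2D", "L"),
                                max_cycles = 3L, grid_span = 16,
                                grid_points = 9L) {
  stopifnot(inherits(defaults, "model_params"),
            inherits(targets, "calibration_target"))
  if (any(c("k3", "d4") %in% free))
    stop("k3 and d4 are held fixed and cannot be calibrated", call. = FALSE)
  bad <- setdiff(free, names(defaults))
  if (length(bad))
    stop("unknown parameters in `free`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cur <- defaults
  ev <- .calib_objective(cur, targets)
  if (!is.finite(ev$obj))
    stop("defaults do not produce a convergent wild-type trajectory",
         call. = FALSE)
  trace <- data.frame(cycle = 0L, parameter = "(defaults)",
                      value = NA_real_, objective = ev$obj,
                      homodimer_pct = ev$metrics$homodimer_pct,
                      complex21_pct = ev$metrics$complex21_pct,
                      stringsAsFactors = FALSE)
  best_obj <- ev$obj
  best_met <- ev$metrics
  if (length(free) && best_obj > targets$tolerance) {
    for (cycle in seq_len(max_cycles)) {
      # re-tie the dimerisation threshold to 60% of the running SCR level
      Cstar <- best_met$terminal[["C"]]
      if (is.finite(Cstar) && Cstar > 0) cur$C0 <- 0.6 * Cstar
      improved <- FALSE
      for (nm in free) {
        span <- grid_span
        for (refine in 1:3) {
          center <- cur[[nm]]
          grid <- center * exp(seq(-log(span), log(span),
                                   length.out = grid_points))
          vals <- vapply(grid, function(v) {
            p <- cur; p[[nm]] <- v
            .calib_objective(p, targets)$obj
          }, numeric(1))
          k <- which.min(vals)
          if (is.finite(vals[k]) && vals[k] < best_obj - 1e-9) {
            cur[[nm]] <- grid[k]
            best_obj <- vals[k]
            best_met <- .calib_objective(cur, targets)$metrics
            improved <- TRUE
            trace <- rbind(trace, data.frame(
              cycle = cycle, parameter = nm, value = grid[k],
              objective = best_obj,
              homodimer_pct = best_met$homodimer_pct,
              complex21_pct = best_met$complex21_pct,
              stringsAsFactors = FALSE))
          }
          span <- exp(log(span) / (grid_points %/% 2))  # shrink around best
          if (best_obj <= targets$tolerance / 4) break
        }
        if (best_obj <= targets$tolerance / 4) break
      }
      if (best_obj <= targets$tolerance / 4 || !improved) break
    }
  }
  structure(list(params = cur,
                 achieved = c(homodimer_pct = best_met$homodimer_pct,
                              complex21_pct = best_met$complex21_pct),
                 objective = best_obj,
                 converged = best_obj <= targets$tolerance,
                 trace = trace, defaults = defaults, targets = targets),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("calibration_fit:", if (x$converged) "converged" else
    "NOT within tolerance", "\n")
  cat("  achieved: homodimer", round(x$achieved[["homodimer_pct"]], 2),
      "% | 2:1 complex", round(x$achieved[["complex21_pct"]], 2), "%\n")
  for (nm in c("d2", "K2D", "L"))
    cat("  ", nm, ": ", signif(x$defaults[[nm]], 4), " -> ",
        signif(x$params[[nm]], 4), "\n", sep = "")
  invisible(x)
}

#' Verify a parameter set against the composition targets
#'
#' Simulates the wild-type model to steady state and compares the two
#' composition percentages with the targets.
#'
#' @param params a `model_params`.
#' @param targets a `calibration_target`.
#' @param t_end integration horizon (hr).
#' @return list with `achieved`, `deviations`, `pass`, and the
#'   steady-state metrics.
#' @export
verify_constraints <- function(params, targets = calibration_target(),
                               t_end = 120) {
  met <- .steady_composition(params, t_end = t_end)
  if (is.null(met))
    return(list(achieved = c(homodimer_pct = NA_real_,
                             complex21_pct = NA_real_),
                deviations = c(NA_real_, NA_real_), pass = FALSE,
                reason = "model failed to integrate"))
  dev <- c(homodimer_pct = met$homodimer_pct - targets$homodimer_pct,
           complex21_pct = met$complex21_pct - targets$complex21_pct)
  list(achieved = c(homodimer_pct = met$homodimer_pct,
                    complex21_pct = met$complex21_pct),
       deviations = dev,
       pass = all(is.finite(dev)) && max(abs(dev)) <= targets$tolerance,
       metrics = met)
}
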