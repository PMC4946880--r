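test_that("the logistic dimerisation switch has the printed shape", {
  expect_equal(k2_of_C(360, L = 0.5, k = 0.1, C0 = 360), 0.25)
  expect_equal(k2_of_C(1e6, L = 0.5, k = 0.1, C0 = 360), 0.5)
  expect_lt(k2_of_C(0, L = 0.5, k = 0.1, C0 = 360), 1e-10)
  expect_true(all(k2_of_C(seq(0, 1000, 50)) > 0))
  expect_true(all(k2_of_C(seq(0, 1000, 50)) <= 0.5))
})

test_that("transport rates are D/A with unit conversion", {
  expect_equal(transport_rate(2.45, 100, "per_s"), 0.0245)
  expect_equal(transport_rate(2.45, 100, "per_hr"), 0.0245 * 3600)
  expect_equal(transport_rate(0, 100), 0)
  expect_equal(transport_rate(2.45, 200), transport_rate(2.45, 100) / 2)
  expect_error(transport_rate(2.45, 0), "positive")
})

test_that("the right-hand side vanishes at the linear-subsystem fixed point", {
  p <- default_model_params()
  Sv_star <- p$k1 / (p$a1 + p$d1)
  Se_star <- p$a1 * Sv_star / p$d2
  st <- c(Sv = Sv_star, Se = Se_star, S2e = 0, C = 0, SC = 0, S2C = 0)
  d <- shr_scr_rhs(st, p, "wildtype")
  expect_equal(d[["Sv"]], 0, tolerance = 1e-12)
  expect_equal(d[["Se"]], 0, tolerance = 1e-12)
  # SCR knockdown: dC/dt is exactly zero whatever the state
  st2 <- c(Sv = 3, Se = 2, S2e = 1, C = 123, SC = 4, S2C = 5)
  expect_identical(shr_scr_rhs(st2, p, "scri")[["C"]], 0)
})

test_that("integrated terminal states match the closed forms", {
  p <- default_model_params()
  traj <- simulate_model(p, t_end = 48)
  terminal <- traj$states[nrow(traj$states), ]
  Sv_star <- p$k1 / (p$a1 + p$d1)
  expect_equal(terminal[["Sv"]], Sv_star, tolerance = 1e-6)
  expect_equal(terminal[["Se"]], p$a1 * Sv_star / p$d2, tolerance = 1e-6)
  # a fixed-point start stays constant
  const <- simulate_model(p, init = traj$states[nrow(traj$states), ],
                          t_end = 5)
  drift <- apply(const$states, 2, function(x) diff(range(x)) /
                   max(abs(x[1]), 1e-9))
  expect_lt(max(drift), 1e-3)
  expect_equal(steady_state_metrics(const)$steady_state_time, 0)
  # no production (k1 = 0) from an all-zero start stays identically zero
  zp <- p; zp$k1 <- 0
  z <- simulate_model(zp, init = stats::setNames(rep(0, 6),
                                                 colnames(traj$states)),
                      t_end = 5)
  expect_equal(max(abs(z$states)), 0)
})

test_that("trajectories stay nonnegative over random parameter draws", {
  set.seed(61)
  base <- default_model_params()
  nm <- c("k1", "a1", "d1", "d2", "d3", "L", "k3", "K1D", "K2D", "d4",
          "k4", "d5", "k5", "d6")
  ok <- TRUE
  for (i in 1:100) {
    p <- base
    for (n in nm) p[[n]] <- base[[n]] * exp(runif(1, -log(4), log(4)))
    traj <- try(simulate_model(p, t_end = 12, dt = 0.25), silent = TRUE)
    if (inherits(traj, "try-error")) next
    if (min(traj$states) < -1e-6) ok <- FALSE
  }
  expect_true(ok)
  expect_error(simulate_model(base, init = c(Sv = -1, Se = 0, S2e = 0,
                                             C = 0, SC = 0, S2C = 0)),
               "nonnegative")
})

test_that("the homodimer waits for SCR to cross its threshold", {
  p <- default_model_params()
  traj <- simulate_model(p, t_end = 36)
  cross <- traj$time[min(which(traj$states[, "C"] >= p$C0))]
  before <- traj$states[traj$time <= cross - 1, "S2e"]
  terminal <- traj$states[nrow(traj$states), "S2e"]
  expect_lt(max(before), 0.05 * terminal)
  # and the 2:1 complex follows the homodimer, not the 1:1 complex
  t_half <- function(v) traj$time[min(which(v >= 0.5 * v[length(v)]))]
  expect_gt(t_half(traj$states[, "S2C"]), t_half(traj$states[, "SC"]))
})

test_that("steady-state metrics report composition percentages", {
  p <- default_model_params()
  traj <- simulate_model(p, t_end = 48)
  m <- steady_state_metrics(traj)
  term <- m$terminal
  expect_equal(m$homodimer_pct,
               100 * term[["S2e"]] / (term[["Se"]] + term[["S2e"]]))
  expect_equal(m$complex21_pct,
               100 * term[["S2C"]] / (term[["SC"]] + term[["S2C"]]))
  # synthetic terminal states give the printed arithmetic
  fake <- traj
  fake$states[nrow(fake$states), ] <- c(1, 92.5, 7.5, 500, 84.8, 15.2)
  fake$states[nrow(fake$states) - 1, ] <- fake$states[nrow(fake$states), ]
  mf <- suppressWarnings(steady_state_metrics(fake))
  expect_equal(mf$homodimer_pct, 7.5)
  expect_equal(mf$complex21_pct, 15.2)
  # unconverged trajectory warns and reports NA
  short <- simulate_model(p, t_end = 2)
  expect_warning(ms <- steady_state_metrics(short, tol = 1e-6))
  expect_true(is.na(ms$steady_state_time))
})

test_that("SCR knockdown mode suppresses homodimer and 2:1 complex", {
  p <- default_model_params("scri")
  expect_equal(p$a2, transport_rate(p$D2, p$A2))
  traj <- simulate_model(p, init = c(Sv = 0, Se = 0, S2e = 0,
                                     C = 0.5 * p$C0, SC = 0, S2C = 0),
                         t_end = 24, mode = "scri")
  m <- suppressWarnings(steady_state_metrics(traj))
  expect_lt(m$homodimer_pct, 1)
  expect_lt(m$terminal[["S2C"]], 0.01 * max(m$terminal[["SC"]], 1e-12))
  expect_equal(m$terminal[["C"]], 0.5 * p$C0)   # held fixed
})
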