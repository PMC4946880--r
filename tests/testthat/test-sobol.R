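test_that("the radial design has the prescribed structure", {
  bounds <- data.frame(parameter = c("a", "b", "c"),
                       lower = c(1, 10, 0.1), upper = c(2, 40, 0.4),
                       log = c(FALSE, TRUE, TRUE))
  set.seed(71)
  des <- generate_design(bounds, N = 4)
  set.seed(71)
  des2 <- generate_design(bounds, N = 4)
  expect_identical(des$A, des2$A)               # reproducible given the seed
  expect_false(isTRUE(all.equal(des$A, des$B))) # A and B independent draws
  for (i in 1:3) {
    expect_identical(des$C[[i]][, i], des$B[, i])
    for (j in setdiff(1:3, i))
      expect_identical(des$C[[i]][, j], des$A[, j])
  }
  expect_true(all(des$A >= rep(bounds$lower, each = 4)))
  expect_true(all(des$A <= rep(bounds$upper, each = 4)))
  bad <- bounds; bad$upper[1] <- bad$lower[1]
  expect_error(generate_design(bad, N = 4), "degenerate")
})

test_that("total-effect indices match the analytic additive decomposition", {
  cs <- c(3, 2, 1, 0.5, 0)
  bounds <- data.frame(parameter = paste0("x", 1:5), lower = 0, upper = 1,
                       log = FALSE)
  f <- function(m) cbind(Y = as.numeric(m %*% cs))
  set.seed(72)
  des <- generate_design(bounds, N = 1000)
  res <- total_effect_indices(f(des$A), lapply(des$C, f))
  analytic <- cs^2 / sum(cs^2)
  expect_lt(max(abs(res$S_T[, 1] - analytic)), 0.05)
  expect_equal(res$S_T["x5", 1], 0, tolerance = 1e-12)  # irrelevant input
  # a function of one parameter only: S_T1 ~ 1, the rest ~ 0
  g <- function(m) cbind(Y = m[, 1]^2)
  res1 <- total_effect_indices(g(des$A), lapply(des$C, g))
  expect_equal(res1$S_T["x1", 1], 1, tolerance = 0.15)
  expect_lt(max(res1$S_T[-1, 1]), 0.01)
  # degenerate outcome variance is an error
  h <- function(m) cbind(Y = rep(1, nrow(m)))
  expect_error(total_effect_indices(h(des$A), lapply(des$C, h)),
               "variance")
})

test_that("the estimator is consistent and exchangeable in B", {
  cs <- c(3, 2, 1, 0.5, 0)
  bounds <- data.frame(parameter = paste0("x", 1:5), lower = 0, upper = 1,
                       log = FALSE)
  f <- function(m) cbind(Y = as.numeric(m %*% cs))
  analytic <- cs^2 / sum(cs^2)
  err_at <- function(N, seed) {
    set.seed(seed)
    des <- generate_design(bounds, N = N)
    res <- total_effect_indices(f(des$A), lapply(des$C, f))
    max(abs(res$S_T[, 1] - analytic))
  }
  err250 <- vapply(1:10, function(s) err_at(250, s), numeric(1))
  err1000 <- vapply(1:10, function(s) err_at(1000, s + 100), numeric(1))
  expect_lt(stats::median(err1000), stats::median(err250))
  # permuting the rows of B leaves the indices unchanged in expectation
  set.seed(73)
  des <- generate_design(bounds, N = 1000)
  perm <- sample.int(1000)
  desp <- des
  desp$B <- des$B[perm, ]
  desp$C <- lapply(seq_along(des$C), function(i) {
    m <- des$A; m[, i] <- desp$B[, i]; m
  })
  r1 <- total_effect_indices(f(des$A), lapply(des$C, f))
  r2 <- total_effect_indices(f(desp$A), lapply(desp$C, f))
  expect_lt(max(abs(r1$S_T - r2$S_T)), 0.06)
})

test_that("model evaluation integrates the six outcomes and flags failures", {
  p <- default_model_params()
  m <- matrix(c(p$k1, p$a1), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("k1", "a1")))
  m[2, "k1"] <- 0
  out <- evaluate_outcomes(m, p, t_end = 6, dt = 0.5,
                           init = c(Sv = 0, Se = 0, S2e = 0, C = 0,
                                    SC = 0, S2C = 0))
  expect_equal(dim(out), c(2L, 6L))
  expect_equal(unname(out[2, ]), rep(0, 6))     # k1 = 0, zero start
  # constant trajectory integrates to c * T
  traj <- simulate_model(p, t_end = 48)
  fp <- traj$states[nrow(traj$states), ]
  out2 <- evaluate_outcomes(matrix(numeric(0), 1, 0), p, t_end = 6,
                            dt = 0.5, init = fp)
  expect_equal(unname(out2[1, ]), unname(fp * 6), tolerance = 1e-4)
})

test_that("normalisation and Steel-Dwass ranking flag clear separations", {
  p <- 15; R <- 10
  mk <- function(vals) {
    s <- matrix(rep(vals, 2), p, 2,
                dimnames = list(paste0("p", 1:p), c("A", "B")))
    structure(list(S_T = s), class = "sobol_result")
  }
  # identical indices: nothing flagged
  same <- lapply(1:R, function(i) mk(rep(0.3, p)))
  nr0 <- normalize_and_rank(same)
  expect_false(any(nr0$influential))
  # one parameter far above the rest in every replicate: flagged
  set.seed(74)
  strong <- lapply(1:R, function(i) {
    v <- rnorm(p, 0.1, 0.01); v[3] <- 1; mk(v)
  })
  nr1 <- normalize_and_rank(strong)
  expect_true(nr1$influential[3, 1])
  expect_false(any(nr1$influential[-3, 1]))
  expect_equal(colnames(nr1$normalized), c("A", "B"))
  # z-normalisation: mean 0, sd 1 across parameters within a replicate
  z <- nr1$normalized[, 1]
  expect_equal(mean(z), 0, tolerance = 1e-8)
  # single replicate: normalisation only
  nr2 <- normalize_and_rank(strong[[1]])
  expect_false(any(nr2$influential))
  expect_equal(nr2$n_replicates, 1)
})

test_that("transport rates rank among the influential parameters for
           vascular SHR", {
  set.seed(75)
  reps <- lapply(1:10, function(i)
    sobol_replicate(N = 32, t_end = 12, dt = 1))
  nr <- normalize_and_rank(reps)
  expect_true(nr$influential["a1", "Sv"])
  expect_true(nr$influential["a2", "Sv"])
  # the parameters the calibration stage treats as estimable rank high for
  # their outcomes
  expect_true(nr$influential["d2", "Se"])
  expect_true(all(c("k3", "d4", "K2D") %in%
                    rownames(nr$influential)[nr$influential[, "C"]]))
})
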