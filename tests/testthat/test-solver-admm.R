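test_that("regression block update satisfies its linear systems exactly", {
  d <- random_regression_instance(p = 4, nt = 3, n = 10, seed = 41)
  ts <- temporal_structure(0.3, 3)
  ctrl <- admm_control(rho = 1.7)
  state <- tmtl:::admm_init(d, ts, ctrl)
  set.seed(41)
  state$W <- matrix(rnorm(12), 4, 3)
  state$A <- matrix(rnorm(12), 4, 3)
  state$B <- matrix(rnorm(8), 4, 2)
  state$C <- matrix(rnorm(12), 4, 3)
  state$D <- matrix(rnorm(8), 4, 2)
  W_new <- tmtl:::admm_update_w_regression(state, d, ts)
  rho <- ctrl$rho
  G <- state$A %*% t(ts$R); K <- state$B %*% t(ts$N)
  L <- state$C %*% t(ts$R); J <- state$D %*% t(ts$N)
  WM <- state$W %*% state$M
  for (i in 1:3) {
    V_i <- crossprod(d$x[[i]]) + rho * (1 + state$M[i, i]) * diag(4)
    q_i <- drop(crossprod(d$x[[i]], d$y[[i]])) - L[, i] + rho * G[, i] -
      J[, i] + rho * K[, i] - rho * (WM[, i] - state$M[i, i] * state$W[, i]) +
      rho * state$W[, i]
    expect_lt(max(abs(V_i %*% W_new[, i] - q_i)), 1e-9)
  }
})

test_that("iterated block update reaches the exact Lagrangian minimizer over W", {
  d <- random_regression_instance(p = 3, nt = 2, n = 8, seed = 42)
  ts <- temporal_structure(0.4, 2)
  ctrl <- admm_control(rho = 0.9)
  state <- tmtl:::admm_init(d, ts, ctrl)
  set.seed(42)
  state$A <- matrix(rnorm(6), 3, 2)
  state$B <- matrix(rnorm(3), 3, 1)
  state$C <- matrix(rnorm(6), 3, 2)
  state$D <- matrix(rnorm(3), 3, 1)
  for (k in 1:5000) state$W <- tmtl:::admm_update_w_regression(state, d, ts)
  # exact minimizer: stack the per-task normal equations with the coupling
  rho <- ctrl$rho
  p <- 3; nt <- 2
  Abig <- matrix(0, p * nt, p * nt)
  rhs <- numeric(p * nt)
  G <- state$A %*% t(ts$R); K <- state$B %*% t(ts$N)
  L <- state$C %*% t(ts$R); J <- state$D %*% t(ts$N)
  for (i in 1:nt) {
    ri <- (i - 1) * p + 1:p
    Abig[ri, ri] <- crossprod(d$x[[i]])
    for (j in 1:nt) {
      cj <- (j - 1) * p + 1:p
      Abig[ri, cj] <- Abig[ri, cj] + rho * state$M[j, i] * diag(p)
    }
    rhs[ri] <- drop(crossprod(d$x[[i]], d$y[[i]])) - L[, i] - J[, i] +
      rho * G[, i] + rho * K[, i]
  }
  W_star <- matrix(solve(Abig, rhs), p, nt)
  expect_lt(max(abs(state$W - W_star)), 1e-6)
})

test_that("auxiliary updates are the stated proximal maps", {
  d <- random_regression_instance(p = 4, nt = 3, n = 10, seed = 43)
  ts <- temporal_structure(0.2, 3)
  ctrl <- admm_control(rho = 2)
  state <- tmtl:::admm_init(d, ts, ctrl)
  set.seed(43)
  state$W <- matrix(rnorm(12), 4, 3)
  state$C <- matrix(rnorm(12), 4, 3)
  state$D <- matrix(rnorm(8), 4, 2)
  # lambda1 = lambda2 = 0: A passes through; lambda3 = 0: B passes through
  aux0 <- tmtl:::admm_update_auxiliary(state, ts, 0, 0, 0)
  expect_equal(aux0$A, state$W %*% ts$R + state$C / 2, tolerance = 1e-12)
  expect_equal(aux0$B, state$W %*% ts$N + state$D / 2, tolerance = 1e-12)
  # generic weights: rows of A solve the sparse-group subproblem
  aux <- tmtl:::admm_update_auxiliary(state, ts, 0.8, 0.6, 0.9)
  VA <- state$W %*% ts$R + state$C / 2
  for (r in 1:4) {
    expect_equal(aux$A[r, ], oracle_row_prox(VA[r, ], 0.8 / 2, 0.6 / 2, 0),
                 tolerance = 1e-6)
  }
  VB <- state$W %*% ts$N + state$D / 2
  expect_equal(aux$B, prox_soft_threshold(VB, 0.9 / 2), tolerance = 1e-12)
})

test_that("dual updates and residuals follow their definitions", {
  d <- random_regression_instance(p = 3, nt = 2, n = 8, seed = 44)
  ts <- temporal_structure(0.3, 2)
  state <- tmtl:::admm_init(d, ts, admm_control(rho = 1.5))
  set.seed(44)
  state$W <- matrix(rnorm(6), 3, 2)
  # feasible state: duals unchanged, primal residual zero
  state$A <- state$W %*% ts$R
  state$B <- state$W %*% ts$N
  duals <- tmtl:::admm_update_duals(state, ts)
  expect_equal(duals$C, state$C)
  expect_equal(duals$D, state$D)
  res <- tmtl:::admm_residuals(state, ts, state$A, state$B)
  expect_equal(res[["primal"]], 0)
  expect_equal(res[["dual"]], 0)
  # one step from zero duals: C = rho (WR - A)
  state$A <- matrix(rnorm(6), 3, 2)
  duals <- tmtl:::admm_update_duals(state, ts)
  expect_equal(duals$C, 1.5 * (state$W %*% ts$R - state$A))
})

test_that("solver converges, agrees with the accelerated method, and rho moves speed not the fixed point", {
  d <- random_regression_instance(p = 4, nt = 3, n = 20, seed = 45)
  agm <- fit_agm(d, 0.2, 0.15, 0.1, alpha = 0.3,
                 control = agm_control(tol = 1e-11, max_iter = 50000))
  objs <- numeric(0); iters <- integer(0)
  for (rho in c(0.5, 1, 5)) {
    f <- fit_admm(d, 0.2, 0.15, 0.1, alpha = 0.3,
                  control = admm_control(rho = rho, tol_primal = 1e-6,
                                         tol_dual = 1e-6, max_iter = 20000))
    expect_true(f$converged)
    objs <- c(objs, tail(f$objective, 1))
    iters <- c(iters, f$n_iter)
    expect_true(all(f$diagnostics$dual_residuals < 1e6))
    expect_lt(tail(f$diagnostics$primal_residuals, 1), 1e-3)
  }
  ref <- tail(agm$objective, 1)
  expect_true(all(abs(objs - ref) / ref < 1e-3))
  # unpenalized limit: per-task least squares
  f0 <- fit_admm(d, 0, 0, 0, alpha = 0.3,
                 control = admm_control(tol_primal = 1e-8, tol_dual = 1e-8,
                                        max_iter = 50000))
  expect_lt(max(abs(f0$W - least_squares_W(d))), 1e-4)
})

test_that("classification block gradient matches finite differences and the solvers agree", {
  set.seed(46)
  xs <- lapply(1:2, function(i) matrix(rnorm(30 * 3), 30, 3))
  ys <- lapply(1:2, function(i) sample(c(-1, 1), 30, replace = TRUE))
  dc <- multitask_data(xs, ys, type = "classification")
  ts <- temporal_structure(0.25, 2)
  state <- tmtl:::admm_init(dc, ts, admm_control(rho = 1.2))
  state$A <- matrix(rnorm(6), 3, 2); state$B <- matrix(rnorm(3), 3, 1)
  state$C <- matrix(rnorm(6), 3, 2); state$D <- matrix(rnorm(3), 3, 1)
  rho <- 1.2
  fn <- function(w) {
    W <- matrix(w, 3, 2)
    RA <- W %*% ts$R - state$A; RB <- W %*% ts$N - state$B
    logistic_loss(W, dc)$value + sum(state$C * RA) + rho / 2 * sum(RA^2) +
      sum(state$D * RB) + rho / 2 * sum(RB^2)
  }
  w0 <- rnorm(6)
  g_an <- {
    W <- matrix(w0, 3, 2)
    RA <- W %*% ts$R - state$A; RB <- W %*% ts$N - state$B
    as.vector(logistic_loss(W, dc)$gradient +
                (state$C + rho * RA) %*% t(ts$R) +
                (state$D + rho * RB) %*% t(ts$N))
  }
  g_fd <- vapply(1:6, function(j) {
    e <- rep(0, 6); e[j] <- 1e-6
    (fn(w0 + e) - fn(w0 - e)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(g_an - g_fd)) / max(1, max(abs(g_an))), 1e-5)

  fa <- fit_agm(dc, 0.05, 0.05, 0.05, alpha = 0.25,
                control = agm_control(tol = 1e-10, max_iter = 50000))
  fd <- fit_admm(dc, 0.05, 0.05, 0.05, alpha = 0.25,
                 control = admm_control(tol_primal = 1e-6, tol_dual = 1e-6,
                                        max_iter = 20000))
  expect_lt(abs(tail(fa$objective, 1) - tail(fd$objective, 1)) /
              tail(fa$objective, 1), 1e-3)
})

test_that("duplicating a sample leaves the averaged data gradient unchanged", {
  set.seed(47)
  X <- matrix(rnorm(10 * 2), 10, 2)
  y <- sample(c(-1, 1), 10, replace = TRUE)
  d1 <- multitask_data(list(X), list(y), type = "classification")
  d2 <- multitask_data(list(rbind(X, X)), list(c(y, y)), type = "classification")
  W <- matrix(rnorm(2), 2, 1)
  expect_equal(logistic_loss(W, d1)$gradient, logistic_loss(W, d2)$gradient,
               tolerance = 1e-12)
})
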