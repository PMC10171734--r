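#' Control parameters for the ADMM solver
#'
#' @param rho Augmented-Lagrangian penalty parameter (`> 0`). The fixed
#'   point does not depend on `rho`; the iteration count does. Values in
#'   `{0.01, 0.1, 1, 2.5, 5}` are typical sweep points.
#' @param max_iter Maximum number of outer iterations.
#' @param tol_primal,tol_dual Absolute stopping tolerances on the primal and
#'   dual residuals.
#' @param inner_tol,inner_iter Tolerance and iteration cap for the
#'   quasi-Newton inner solve of the coefficient block under the logistic
#'   loss (ignored for regression, where the block update is a cached
#'   Cholesky solve).
#' @return A list of class `"admm_control"`.
#' @export
admm_control <- function(rho = 1, max_iter = 5000L,
                         tol_primal = 1e-4, tol_dual = 1e-4,
                         inner_tol = 1e-6, inner_iter = 50L) {
  if (!is.numeric(rho) || rho <= 0) abort("`rho` must be positive.")
  check_count(max_iter, min = 1, what = "max_iter")
  structure(list(rho = rho, max_iter = as.integer(max_iter),
                 tol_primal = tol_primal, tol_dual = tol_dual,
                 inner_tol = inner_tol, inner_iter = as.integer(inner_iter)),
            class = "admm_control")
}

# Internal mutable state for one ADMM run. A (p x t) and B (p x (t-1))
# relax the constraints W R = A and W R H = B; C, D are the duals.
admm_init <- function(data, ts, control) {
  p <- data$n_features
  nt <- data$n_tasks
  rho <- control$rho
  E <- ts$R %*% t(ts$R)
  FF <- ts$N %*% t(ts$N)
  M <- E + FF
  chol_factors <- NULL
  if (data$type == "regression") {
    chol_factors <- lapply(seq_len(nt), function(i) {
      V <- crossprod(data$x[[i]]) + rho * (1 + M[i, i]) * diag(p)
      chol(V)   # succeeds iff V is positive definite
    })
  }
  list(
    W = matrix(0, p, nt), A = matrix(0, p, nt),
    B = matrix(0, p, max(nt - 1L, 0L)),
    C = matrix(0, p, nt), D = matrix(0, p, max(nt - 1L, 0L)),
    rho = rho, M = M, chol_factors = chol_factors
  )
}

# Linearized (Jacobi) block update of W for the squared loss: each task
# column solves V_i w_i = q_i with V_i = X_i'X_i + rho (1 + M_ii) I cached
# as a Cholesky factor. The q_i carries the proximal anchor rho * w_i^k that
# matches the extra rho I in V_i, so the scheme's fixed point is the exact
# minimizer of the augmented Lagrangian over W.
admm_update_w_regression <- function(state, data, ts) {
  rho <- state$rho
  G <- state$A %*% t(ts$R)
  K <- state$B %*% t(ts$N)
  L <- state$C %*% t(ts$R)
  J <- state$D %*% t(ts$N)
  WM <- state$W %*% state$M
  W_new <- state$W
  for (i in seq_len(data$n_tasks)) {
    q_i <- crossprod(data$x[[i]], data$y[[i]]) - L[, i] + rho * G[, i] -
      J[, i] + rho * K[, i] -
      rho * (WM[, i] - state$M[i, i] * state$W[, i]) +
      rho * state$W[, i]
    U <- state$chol_factors[[i]]
    W_new[, i] <- backsolve(U, forwardsolve(t(U), q_i))
  }
  W_new
}

# W block under the logistic loss: quasi-Newton (L-BFGS-B) minimization of
# loss(W) + <C, WR - A> + rho/2 ||WR - A||^2 + <D, WRH - B> + rho/2 ||WRH - B||^2
admm_update_w_classification <- function(state, data, ts, control) {
  rho <- state$rho
  p <- data$n_features
  nt <- data$n_tasks
  fn <- function(w) {
    W <- matrix(w, p, nt)
    RA <- W %*% ts$R - state$A
    RB <- W %*% ts$N - state$B
    logistic_loss(W, data)$value + sum(state$C * RA) + rho / 2 * sum(RA^2) +
      sum(state$D * RB) + rho / 2 * sum(RB^2)
  }
  gr <- function(w) {
    W <- matrix(w, p, nt)
    RA <- W %*% ts$R - state$A
    RB <- W %*% ts$N - state$B
    G <- logistic_loss(W, data)$gradient +
      (state$C + rho * RA) %*% t(ts$R) +
      (state$D + rho * RB) %*% t(ts$N)
    as.vector(G)
  }
  res <- optim(as.vector(state$W), fn, gr, method = "L-BFGS-B",
               control = list(maxit = control$inner_iter,
                              factr = control$inner_tol / .Machine$double.eps))
  if (!res$convergence %in% c(0L, 1L)) {
    abort(sprintf("inner quasi-Newton solve failed (code %d): %s",
                  res$convergence, res$message))
  }
  matrix(res$par, p, nt)
}

# Auxiliary updates: A by the row-wise sparse-group prox of W R + C/rho,
# B by elementwise soft-thresholding of W R H + D/rho.
admm_update_auxiliary <- function(state, ts, lambda1, lambda2, lambda3) {
  rho <- state$rho
  VA <- state$W %*% ts$R + state$C / rho
  A <- VA
  for (r in seq_len(nrow(VA))) {
    A[r, ] <- prox_sparse_group(VA[r, ], lambda1 / rho, lambda2 / rho)
  }
  B <- state$B
  if (ncol(B) > 0L) {
    B <- prox_soft_threshold(state$W %*% ts$N + state$D / rho, lambda3 / rho)
  }
  list(A = A, B = B)
}

admm_update_duals <- function(state, ts) {
  C <- state$C + state$rho * (state$W %*% ts$R - state$A)
  D <- state$D
  if (ncol(D) > 0L) D <- state$D + state$rho * (state$W %*% ts$N - state$B)
  list(C = C, D = D)
}

# Primal and dual residuals, exactly in the forms
# P = ||WR - A||_F + ||WRH - B||_F ,
# S = ||rho (A_new - A_old) + rho (B_new - B_old) H'||_F .
admm_residuals <- function(state, ts, A_old, B_old) {
  primal <- frob(state$W %*% ts$R - state$A)
  if (ncol(state$B) > 0L) primal <- primal + frob(state$W %*% ts$N - state$B)
  dual_mat <- state$rho * (state$A - A_old)
  if (ncol(state$B) > 0L) {
    dual_mat <- dual_mat + state$rho * (state$B - B_old) %*% t(ts$H)
  }
  c(primal = primal, dual = frob(dual_mat))
}

frob <- function(m) sqrt(sum(m^2))

#' Fit by inexact ADMM
#'
#' Splits the temporal multi-task program with auxiliary variables
#' `A = W R` (carrying both the L1 and the group penalty) and `B = W R H`
#' (the fusion penalty), and alternates: a linearized per-task coefficient
#' update (cached Cholesky solves for regression, quasi-Newton for the
#' logistic loss), closed-form proximal updates of `A` and `B`, and standard
#' dual ascent. Stops when both the primal residual
#' `||WR - A||_F + ||WRH - B||_F` and the dual residual
#' `||rho dA + rho dB H'||_F` fall below their tolerances.
#'
#' @inheritParams fit_agm
#' @param control An [admm_control()].
#' @return A `"tmtl_fit"` object with residual traces in `diagnostics`.
#' @export
fit_admm <- function(data, lambda1, lambda2, lambda3, alpha = 0.3, ts = NULL,
                     control = admm_control()) {
  stopifnot(inherits(data, "multitask_data"), inherits(control, "admm_control"))
  check_nonneg(lambda1, "lambda1")
  check_nonneg(lambda2, "lambda2")
  check_nonneg(lambda3, "lambda3")
  if (is.null(ts)) ts <- temporal_structure(alpha, data$n_tasks)
  stopifnot(inherits(ts, "temporal_structure"))
  if (ts$n_tasks != data$n_tasks) abort("`ts` and `data` disagree on the number of tasks.")

  state <- admm_init(data, ts, control)
  obj <- objective_value(state$W, data, ts, lambda1, lambda2, lambda3)
  trace <- numeric(control$max_iter + 1L)
  trace[1L] <- obj
  primal_trace <- dual_trace <- numeric(control$max_iter)
  converged <- FALSE
  n_iter <- 0L

  for (k in seq_len(control$max_iter)) {
    state$W <- if (data$type == "regression") {
      admm_update_w_regression(state, data, ts)
    } else {
      admm_update_w_classification(state, data, ts, control)
    }
    if (!all(is.finite(state$W))) abort("ADMM diverged (non-finite coefficients).")
    A_old <- state$A
    B_old <- state$B
    aux <- admm_update_auxiliary(state, ts, lambda1, lambda2, lambda3)
    state$A <- aux$A
    state$B <- aux$B
    duals <- admm_update_duals(state, ts)
    state$C <- duals$C
    state$D <- duals$D
    res <- admm_residuals(state, ts, A_old, B_old)
    n_iter <- k
    primal_trace[k] <- res[["primal"]]
    dual_trace[k] <- res[["dual"]]
    trace[k + 1L] <- objective_value(state$W, data, ts, lambda1, lambda2, lambda3)
    if (res[["primal"]] < control$tol_primal && res[["dual"]] < control$tol_dual) {
      converged <- TRUE
      break
    }
  }

  new_tmtl_fit(
    W = state$W, data = data, ts = ts,
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    objective = trace[seq_len(n_iter + 1L)],
    n_iter = n_iter, converged = converged, solver = "admm",
    diagnostics = list(
      rho = control$rho,
      primal_residuals = primal_trace[seq_len(n_iter)],
      dual_residuals = dual_trace[seq_len(n_iter)],
      control = unclass(control)
    )
  )
}
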