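#' Momentum schedule for the accelerated solver
#'
#' The accelerated solver interpolates a search point between successive
#' iterates, `S_{i+1} = W_i + alpha_i (W_i - W_{i-1})`, with
#' `alpha_i = (t_{i-1} - 1) / t_i`, `t_0 = 1` and
#' `t_i = (1 + sqrt(4 t_{i-1}^2 + 1)) / 2`. This is the standard schedule
#' giving the optimal `O(1/k^2)` first-order rate; the first step has no
#' momentum (`alpha_1 = 0`).
#'
#' @param iterations Number of steps to tabulate.
#' @return A tibble with columns `iter`, `t`, `alpha`.
#' @examples
#' momentum_schedule(3)
#' @export
momentum_schedule <- function(iterations) {
  check_count(iterations, min = 1, what = "iterations")
  t_prev <- 1
  out <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    t_i <- 0.5 * (1 + sqrt(4 * t_prev^2 + 1))
    out[[i]] <- c(iter = i, t = t_i, alpha = (t_prev - 1) / t_i)
    t_prev <- t_i
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Control parameters for the accelerated solver
#'
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance on the change of the objective between
#'   consecutive accepted iterates.
#' @param monitor `"relative"` (default; change divided by the previous
#'   value) or `"absolute"`.
#' @param line_search If `TRUE` (default) the step size is backtracked:
#'   `L` is doubled until the quadratic upper bound
#'   `f(W) <= f(S) + <grad f(S), W - S> + L/2 ||W - S||_F^2` holds at the
#'   prox candidate. If `FALSE`, the initial `L` is used throughout.
#' @param lipschitz Optional override for the initial Lipschitz estimate.
#'   Default: the spectral bound of the loss times the squared spectral
#'   norm of the inverse structure matrix (the reparameterized smooth part
#'   is a function of `Q = W R`).
#' @param init Optional initial `p x t` matrix for `Q = W R` (default zero).
#' @return A list of class `"agm_control"`.
#' @export
agm_control <- function(max_iter = 10000L, tol = 1e-4,
                        monitor = c("relative", "absolute"),
                        line_search = TRUE, lipschitz = NULL, init = NULL) {
  monitor <- arg_match(monitor)
  check_count(max_iter, min = 1, what = "max_iter")
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be positive.")
  structure(list(max_iter = as.integer(max_iter), tol = tol, monitor = monitor,
                 line_search = isTRUE(line_search), lipschitz = lipschitz,
                 init = init),
            class = "agm_control")
}

#' Fit by accelerated proximal gradient
#'
#' Solves the temporal multi-task program by reparameterizing to the
#' temporal tasks `Q = W R`: since `R` is invertible, the objective becomes
#' `loss(Q R^{-1}) + lambda1 ||Q||_1 + lambda2 ||Q||_{1,2} +
#' lambda3 ||(Q H)^T||_1`, whose non-smooth part decouples over the rows of
#' `Q` and admits an exact proximal operator ([prox_matrix_rows()]). Each
#' iteration takes a gradient step of the smooth part from the momentum
#' search point, applies the prox, and (monotone safeguard) keeps the
#' previous iterate if the candidate would increase the objective, so the
#' monitored objective trace is non-increasing. The candidate sequence still
#' drives the momentum, preserving the accelerated rate.
#'
#' @param data A [multitask_data()].
#' @param ts A [temporal_structure()] with matching `n_tasks`; alternatively
#'   pass `alpha` and it is built internally.
#' @param lambda1,lambda2,lambda3 Non-negative penalty weights.
#' @param alpha Relational degree in `[0, 0.5]`, used when `ts` is `NULL`.
#' @param control An [agm_control()].
#' @return A `"tmtl_fit"` object; see [tmtl_fit()] for the fields.
#' @export
fit_agm <- function(data, lambda1, lambda2, lambda3, alpha = 0.3, ts = NULL,
                    control = agm_control()) {
  stopifnot(inherits(data, "multitask_data"), inherits(control, "agm_control"))
  check_nonneg(lambda1, "lambda1")
  check_nonneg(lambda2, "lambda2")
  check_nonneg(lambda3, "lambda3")
  if (is.null(ts)) ts <- temporal_structure(alpha, data$n_tasks)
  stopifnot(inherits(ts, "temporal_structure"))
  if (ts$n_tasks != data$n_tasks) abort("`ts` and `data` disagree on the number of tasks.")

  p <- data$n_features
  nt <- data$n_tasks
  S_inv <- ts$R_inv
  loss <- loss_fn(data)

  # smooth part in Q-space: f(Q) = loss(Q %*% R_inv)
  f_grad <- function(Q) {
    l <- loss(Q %*% S_inv, data)
    list(value = l$value, gradient = l$gradient %*% t(S_inv))
  }
  g_val <- function(Q) {
    fusion <- if (nt >= 2L) sum(abs(Q %*% ts$H)) else 0
    lambda1 * sum(abs(Q)) + lambda2 * sum(sqrt(rowSums(Q^2))) + lambda3 * fusion
  }

  L <- control$lipschitz
  if (is.null(L)) {
    sig_inv2 <- svd(S_inv, nu = 0, nv = 0)$d[1L]^2
    base <- if (data$type == "regression") {
      lipschitz_bound(data)
    } else {
      # logistic curvature is at most 1/4; loss is averaged per task
      max(vapply(seq_len(nt), function(i) {
        svd(data$x[[i]], nu = 0, nv = 0)$d[1L]^2 / (4 * data$n_obs[i])
      }, numeric(1)))
    }
    L <- base * sig_inv2
  }
  if (!is.finite(L) || L <= 0) L <- 1

  Q <- control$init
  if (is.null(Q)) Q <- matrix(0, p, nt)
  stopifnot(nrow(Q) == p, ncol(Q) == nt)

  x_prev <- Q          # accepted iterate i-1
  x_cur <- Q           # accepted iterate i
  z_prev <- Q          # prox candidate i-1
  t_prev <- 1
  F_cur <- f_grad(Q)$value + g_val(Q)
  trace <- numeric(control$max_iter + 1L)
  trace[1L] <- F_cur
  converged <- FALSE
  n_iter <- 0L

  for (i in seq_len(control$max_iter)) {
    t_i <- 0.5 * (1 + sqrt(4 * t_prev^2 + 1))
    a_i <- (t_prev - 1) / t_i
    # search point: accepted iterate plus momentum along both sequences
    Sp <- x_cur + (t_prev / t_i) * (z_prev - x_cur) + a_i * (x_cur - x_prev)
    fs <- f_grad(Sp)
    if (!is.finite(fs$value)) abort("objective diverged (non-finite smooth value).")
    repeat {
      Z <- prox_matrix_rows(Sp - fs$gradient / L, lambda1 / L, lambda2 / L, lambda3 / L)
      fz <- loss(Z %*% S_inv, data)$value
      if (!control$line_search) break
      gap <- fs$value + sum(fs$gradient * (Z - Sp)) + L / 2 * sum((Z - Sp)^2)
      if (fz <= gap + 1e-12 * max(1, abs(fz))) break
      L <- 2 * L
      if (!is.finite(L)) abort("line search failed: step size underflow.")
    }
    F_z <- fz + g_val(Z)
    # monotone acceptance: never let the monitored objective increase
    if (F_z <= F_cur) {
      x_prev <- x_cur
      x_cur <- Z
      F_new <- F_z
    } else {
      x_prev <- x_cur
      F_new <- F_cur
    }
    z_prev <- Z
    t_prev <- t_i
    n_iter <- i
    trace[i + 1L] <- F_new
    # stop on the candidate's change, not the accepted one: a rejected
    # overshoot mid-run must not register as zero progress
    delta <- abs(F_z - F_cur)
    if (control$monitor == "relative") delta <- delta / max(abs(F_cur), .Machine$double.eps)
    F_cur <- F_new
    if (delta < control$tol) {
      converged <- TRUE
      break
    }
  }

  W <- x_cur %*% S_inv
  new_tmtl_fit(
    W = W, data = data, ts = ts,
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    objective = trace[seq_len(n_iter + 1L)],
    n_iter = n_iter, converged = converged, solver = "agm",
    diagnostics = list(final_step = 1 / L, lipschitz = L,
                       control = unclass(control))
  )
}
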