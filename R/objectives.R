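#' Loss functions, penalty and full objective
#'
#' The model minimizes `loss(W) + penalty(W)` over the `p x t` coefficient
#' matrix `W`. The regression loss is `0.5 * sum_i ||X_i w_i - y_i||^2`; the
#' classification loss is the per-task-averaged logistic loss
#' `sum_i (1/n_i) sum_j log(1 + exp(-y_ij * x_ij' w_i))` with labels in
#' `{-1, +1}`. The penalty couples tasks through the temporal structure
#' matrix `R` and difference operator `H`:
#' \deqn{\lambda_1 \|WR\|_1 + \lambda_2 \|WR\|_{1,2} + \lambda_3 \|(WRH)^T\|_1,}
#' where \eqn{\|\cdot\|_{1,2}} is the sum over features of the L2 norm of the
#' feature's row — a temporal sparse group Lasso on the temporal tasks `WR`
#' plus a fused Lasso on their consecutive differences.
#'
#' The `1/2` factor on the squared loss and the `1/n_i` averaging of the
#' logistic loss are used consistently in both solvers, so a given set of
#' penalty weights means the same thing whichever solver is selected.
#'
#' @param W `p x t` coefficient matrix.
#' @param data A [multitask_data()] object.
#' @param ts A [temporal_structure()] whose `n_tasks` matches `data`.
#' @param lambda1,lambda2,lambda3 Non-negative penalty weights (L1, group,
#'   fusion).
#' @return `squared_loss()` and `logistic_loss()` return
#'   `list(value =, gradient =)` with the `p x t` gradient;
#'   `penalty_value()` and `objective_value()` return a single number.
#' @name objectives
NULL

#' @rdname objectives
#' @export
squared_loss <- function(W, data) {
  stopifnot(inherits(data, "multitask_data"))
  if (data$type != "regression") abort("squared loss requires a regression dataset.")
  check_conformable(W, data)
  G <- W * 0
  value <- 0
  for (i in seq_len(data$n_tasks)) {
    r <- data$x[[i]] %*% W[, i] - data$y[[i]]
    value <- value + 0.5 * sum(r^2)
    G[, i] <- crossprod(data$x[[i]], r)
  }
  list(value = value, gradient = G)
}

#' @rdname objectives
#' @export
logistic_loss <- function(W, data) {
  stopifnot(inherits(data, "multitask_data"))
  if (data$type != "classification") abort("logistic loss requires a classification dataset.")
  check_conformable(W, data)
  G <- W * 0
  value <- 0
  for (i in seq_len(data$n_tasks)) {
    n_i <- data$n_obs[i]
    m <- data$y[[i]] * drop(data$x[[i]] %*% W[, i])   # margins
    # log(1 + exp(-m)) computed stably for both large positive and negative m
    value <- value + sum(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m)))) / n_i
    sig <- ifelse(m > 0, exp(-m) / (1 + exp(-m)), 1 / (1 + exp(m)))
    G[, i] <- -crossprod(data$x[[i]], data$y[[i]] * sig) / n_i
  }
  list(value = value, gradient = G)
}

loss_fn <- function(data) {
  if (data$type == "regression") squared_loss else logistic_loss
}

#' @rdname objectives
#' @export
penalty_value <- function(W, ts, lambda1, lambda2, lambda3) {
  stopifnot(inherits(ts, "temporal_structure"))
  Q <- W %*% ts$R
  fusion <- if (ts$n_tasks >= 2L) sum(abs(Q %*% ts$H)) else 0
  lambda1 * sum(abs(Q)) +
    lambda2 * sum(sqrt(rowSums(Q^2))) +
    lambda3 * fusion
}

#' @rdname objectives
#' @export
objective_value <- function(W, data, ts, lambda1, lambda2, lambda3) {
  loss_fn(data)(W, data)$value + penalty_value(W, ts, lambda1, lambda2, lambda3)
}

#' Lipschitz bound for the squared-loss gradient
#'
#' The gradient of the per-task squared loss over `W` is Lipschitz with
#' constant `sigma_X^2`, where `sigma_X` is the largest singular value over
#' all per-task design matrices. Used to initialize the accelerated solver's
#' step size `1/L`.
#'
#' @param data A regression [multitask_data()].
#' @return A single non-negative number.
#' @export
lipschitz_bound <- function(data) {
  stopifnot(inherits(data, "multitask_data"))
  if (data$type != "regression") abort("the spectral Lipschitz bound applies to the squared loss.")
  max(vapply(data$x, function(X) svd(X, nu = 0, nv = 0)$d[1L], numeric(1)))^2
}
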