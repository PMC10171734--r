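#' Adaptive global temporal structure matrix
#'
#' Builds the upper-triangular task-coupling matrix `R(alpha)` for `t` ordered
#' time points. Column `i` of `R(alpha)` holds the weights with which the
#' i-th *temporal* coefficient vector mixes the raw per-time-point
#' coefficients: the temporal vectors satisfy the recursion
#' \eqn{\bar\omega_1 = w_1}, \eqn{\bar\omega_i = \alpha\,\bar\omega_{i-1} +
#' (1-\alpha)\,w_i}, so that `W %*% R` stacks them column-wise. `alpha` in
#' `[0, 0.5]` is the relational degree between a time point and its whole
#' history: 0 decouples the tasks (identity matrix), 0.5 weights the current
#' state equal to the accumulated past.
#'
#' Equivalently `R(alpha)` is the product `A_1 ... A_{t-1}` where `A_i` is the
#' identity except `A_i[i, i+1] = alpha`, `A_i[i+1, i+1] = 1 - alpha`.
#' Every column sums to 1 and is non-negative and non-decreasing over its
#' support, so each temporal task is a convex combination of the current and
#' all earlier raw tasks, with influence decaying with temporal distance.
#'
#' @param alpha Relational degree, a single number in `[0, 0.5]`.
#' @param n_tasks Number of time points `t` (positive integer).
#' @return A `t x t` upper-triangular numeric matrix with unit column sums.
#' @examples
#' agts_matrix(0.3, 2)          # [1, 0.3; 0, 0.7]
#' colSums(agts_matrix(0.4, 6)) # all 1
#' @seealso [agts_column_weights()], [temporal_structure()]
#' @export
agts_matrix <- function(alpha, n_tasks) {
  check_alpha(alpha)
  check_count(n_tasks, min = 1, what = "n_tasks")
  t <- as.integer(n_tasks)
  R <- diag(1, t)
  if (t == 1L) return(R)
  # column recursion r_1 = e_1, r_i = alpha * r_{i-1} + (1 - alpha) * e_i
  for (i in 2:t) {
    R[, i] <- alpha * R[, i - 1L]
    R[i, i] <- R[i, i] + (1 - alpha)
  }
  R
}

#' Closed-form column of the temporal structure matrix
#'
#' Column `i` of [agts_matrix()] in closed form: the first entry is
#' `alpha^(i-1)`, entries `2..i` are `alpha^(i-k) * (1-alpha)`, and entries
#' below row `i` are zero. Provided as an independent code path against the
#' product/recursion construction.
#'
#' @inheritParams agts_matrix
#' @param i Task (time point) index, `1 <= i <= n_tasks`.
#' @return Numeric vector of length `n_tasks` summing to 1.
#' @export
agts_column_weights <- function(alpha, i, n_tasks) {
  check_alpha(alpha)
  check_count(n_tasks, min = 1, what = "n_tasks")
  check_count(i, min = 1, what = "i")
  if (i > n_tasks) {
    abort(sprintf("`i` (%d) must not exceed `n_tasks` (%d).", i, n_tasks))
  }
  r <- numeric(n_tasks)
  r[1L] <- alpha^(i - 1L)
  if (i >= 2L) {
    k <- 2:i
    r[k] <- alpha^(i - k) * (1 - alpha)
  }
  r
}

#' Temporal difference operator
#'
#' The `t x (t-1)` matrix `H` with `H[j, j] = 1` and `H[j+1, j] = -1`, so
#' that for a coefficient matrix `W` the product `W %*% R %*% H` has as its
#' j-th column the difference of consecutive temporal tasks
#' \eqn{\bar\omega_j - \bar\omega_{j+1}}. The L1 norm of that product is the
#' global temporal smoothness (fused Lasso) penalty.
#'
#' @param n_tasks Number of time points, at least 2.
#' @return A `t x (t-1)` matrix with zero column sums.
#' @export
temporal_difference_matrix <- function(n_tasks) {
  check_count(n_tasks, min = 2, what = "n_tasks")
  t <- as.integer(n_tasks)
  H <- matrix(0, t, t - 1L)
  for (j in seq_len(t - 1L)) {
    H[j, j] <- 1
    H[j + 1L, j] <- -1
  }
  H
}

#' Invert the temporal structure matrix
#'
#' `R(alpha)` is upper triangular with diagonal `(1, 1-alpha, ..., 1-alpha)`,
#' hence full rank for `alpha < 1`. The inverse is computed by triangular
#' back-substitution ([backsolve()]), not generic inversion.
#'
#' @param R An upper-triangular matrix produced by [agts_matrix()].
#' @return The inverse matrix, satisfying `max(abs(R %*% inv - I)) <= 1e-10`.
#' @export
invert_agts <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (any(abs(diag(R)) < 1e-12)) {
    abort("`R` has a (numerically) zero diagonal entry and cannot be inverted.")
  }
  backsolve(R, diag(1, nrow(R)))
}

#' Bundle of temporal coupling matrices
#'
#' Convenience container computed once per fit: the structure matrix `R`,
#' its inverse, the difference operator `H` and their product `N = R %*% H`.
#' For `n_tasks = 1` there are no temporal differences and `H`, `N` are
#' `1 x 0` matrices.
#'
#' @inheritParams agts_matrix
#' @return An object of class `"temporal_structure"` with fields `alpha`,
#'   `n_tasks`, `R`, `R_inv`, `H`, `N`.
#' @examples
#' ts <- temporal_structure(0.3, 4)
#' max(abs(ts$R %*% ts$R_inv - diag(4)))
#' @export
temporal_structure <- function(alpha, n_tasks) {
  R <- agts_matrix(alpha, n_tasks)
  t <- nrow(R)
  H <- if (t >= 2L) temporal_difference_matrix(t) else matrix(0, 1L, 0L)
  structure(
    list(
      alpha = alpha,
      n_tasks = t,
      R = R,
      R_inv = invert_agts(R),
      H = H,
      N = R %*% H
    ),
    class = "temporal_structure"
  )
}

#' @export
print.temporal_structure <- function(x, ...) {
  cat(sprintf(
    "<temporal_structure> alpha = %g, %d time point%s\n",
    x$alpha, x$n_tasks, if (x$n_tasks == 1L) "" else "s"
  ))
  invisible(x)
}

# ---- input checks (shared across modules) -----------------------------------

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 0.5) {
    abort("`alpha` must be a single number in [0, 0.5].")
  }
  invisible(alpha)
}

check_count <- function(x, min, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", what, min))
  }
  invisible(x)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", what))
  }
  invisible(x)
}
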