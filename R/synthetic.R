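#' Specification for synthetic progression data
#'
#' Describes a ground-truth coefficient structure and sampling scheme that
#' emulate a longitudinal cohort: a shared feature space, per-time-point
#' sample counts that shrink over time (attrition), a small set of features
#' relevant at every time point whose effects drift smoothly, and optional
#' per-time-point idiosyncratic features. The default sample counts
#' `(120, 110, 100, 90, 60, 50)` echo the attrition profile of a multi-year
#' cohort at roughly one-tenth scale.
#'
#' @param p Number of shared features.
#' @param n Integer vector of per-time-point sample counts; its length sets
#'   the number of tasks.
#' @param s_shared Number of features active at every time point.
#' @param s_task Number of extra features each active at a single time point.
#' @param smooth_step Column-to-column drift scale of the active
#'   coefficients (0 = constant effects over time).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   regression targets (classification labels are drawn from the logistic
#'   model instead).
#' @param type `"regression"` or `"classification"`.
#' @param seed Integer seed; all generator randomness flows through it.
#' @return A list of class `"progression_spec"`.
#' @export
progression_spec <- function(p = 30L, n = c(120L, 110L, 100L, 90L, 60L, 50L),
                             s_shared = 6L, s_task = 0L, smooth_step = 0.1,
                             noise_sd = 0.5,
                             type = c("regression", "classification"),
                             seed = 1L) {
  type <- arg_match(type)
  check_count(p, min = 1, what = "p")
  if (!is.numeric(n) || length(n) < 1L || any(n < 1) || any(n != as.integer(n))) {
    abort("`n` must be a vector of positive integer sample counts.")
  }
  check_count(s_shared, min = 0, what = "s_shared")
  check_count(s_task, min = 0, what = "s_task")
  check_nonneg(smooth_step, "smooth_step")
  check_nonneg(noise_sd, "noise_sd")
  if (s_shared + s_task > p) {
    abort("`s_shared + s_task` must not exceed `p`.")
  }
  structure(
    list(p = as.integer(p), n = as.integer(n), t = length(n),
         s_shared = as.integer(s_shared), s_task = as.integer(s_task),
         smooth_step = smooth_step, noise_sd = noise_sd,
         type = type, seed = as.integer(seed)),
    class = "progression_spec"
  )
}

#' Ground-truth coefficient matrix for a synthetic cohort
#'
#' Draws the `p x t` truth: `s_shared` support rows are chosen at random;
#' their first-column values are standard normal and each later column adds
#' `smooth_step` times a fresh standard-normal perturbation on the support —
#' a temporally smooth random walk. `s_task` further rows are each active in
#' one task only. All remaining entries are exactly zero.
#'
#' @param spec A [progression_spec()].
#' @param reseed If `TRUE` (default) the spec's seed is set first; internal
#'   callers that have already seeded pass `FALSE`.
#' @return A list: `W` (`p x t` matrix) and `support` (logical length-`p`
#'   mask of rows that are nonzero anywhere).
#' @export
make_true_coefficients <- function(spec, reseed = TRUE) {
  stopifnot(inherits(spec, "progression_spec"))
  if (reseed) set.seed(spec$seed)
  W <- matrix(0, spec$p, spec$t)
  rows <- sample(spec$p, spec$s_shared + spec$s_task)
  shared <- rows[seq_len(spec$s_shared)]
  if (spec$s_shared > 0L) {
    W[shared, 1L] <- rnorm(spec$s_shared)
    if (spec$t >= 2L) {
      for (k in 2:spec$t) {
        W[shared, k] <- W[shared, k - 1L] + spec$smooth_step * rnorm(spec$s_shared)
      }
    }
  }
  if (spec$s_task > 0L) {
    extra <- rows[spec$s_shared + seq_len(spec$s_task)]
    for (r in extra) {
      W[r, sample(spec$t, 1L)] <- rnorm(1L)
    }
  }
  list(W = W, support = rowSums(abs(W)) > 0)
}

#' Simulate a progression-structured multi-task dataset
#'
#' Design entries are i.i.d. standard normal. Regression targets are
#' `X_i w*_i + noise_sd * eps`; classification labels are drawn from the
#' logistic model at `X_i w*_i` and coded `{-1, +1}`. Fully reproducible
#' from the spec's seed.
#'
#' @param spec A [progression_spec()].
#' @return A list: `data` (long tibble with `task`, `y`, features `x1..xp`),
#'   `mtd` (the equivalent [multitask_data()]), `W` (true coefficients) and
#'   `support` (true row support mask).
#' @examples
#' sim <- simulate_progression(progression_spec(p = 5, n = c(20, 20), seed = 7))
#' dim(sim$W)
#' @export
simulate_progression <- function(spec) {
  stopifnot(inherits(spec, "progression_spec"))
  set.seed(spec$seed)
  truth <- make_true_coefficients(spec, reseed = FALSE)
  xs <- vector("list", spec$t)
  ys <- vector("list", spec$t)
  for (i in seq_len(spec$t)) {
    X <- matrix(rnorm(spec$n[i] * spec$p), spec$n[i], spec$p)
    colnames(X) <- paste0("x", seq_len(spec$p))
    eta <- drop(X %*% truth$W[, i])
    ys[[i]] <- if (spec$type == "regression") {
      eta + spec$noise_sd * rnorm(spec$n[i])
    } else {
      ifelse(runif(spec$n[i]) < stats::plogis(eta), 1, -1)
    }
    xs[[i]] <- X
  }
  mtd <- multitask_data(xs, ys, type = spec$type)
  list(data = as_tibble.multitask_data(mtd), mtd = mtd,
       W = truth$W, support = truth$support)
}
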