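new_tmtl_fit <- function(W, data, ts, lambda1, lambda2, lambda3,
                         objective, n_iter, converged, solver, diagnostics) {
  dimnames(W) <- list(data$feature_names, paste0("task", seq_len(ncol(W))))
  structure(
    list(
      W = W,
      type = data$type,
      n_tasks = data$n_tasks,
      n_features = data$n_features,
      n_obs = data$n_obs,
      alpha = ts$alpha,
      lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
      objective = objective,
      n_iter = n_iter,
      converged = converged,
      solver = solver,
      diagnostics = diagnostics
    ),
    class = "tmtl_fit"
  )
}

#' Fit a temporal multi-task model
#'
#' The front door of the package: takes a long-format tibble (one row per
#' sample, with a time-point column, a target column and shared numeric
#' features), converts it to the per-task representation, and minimizes
#' \deqn{\mathrm{loss}(W) + \lambda_1\|WR\|_1 + \lambda_2\|WR\|_{1,2} +
#'   \lambda_3\|(WRH)^T\|_1}
#' with the chosen solver. See [fit_agm()] and [fit_admm()] for the solver
#' mechanics and [objectives] for the loss/penalty conventions.
#'
#' @inheritParams as_multitask_data
#' @param data A long-format data frame, or a ready-made [multitask_data()].
#' @param lambda1,lambda2,lambda3 Non-negative penalty weights for the L1,
#'   group (row-wise L2) and temporal-fusion penalties.
#' @param alpha Relational degree of the temporal structure, in `[0, 0.5]`.
#' @param solver `"agm"` (accelerated proximal gradient, default) or
#'   `"admm"`.
#' @param control Solver control: [agm_control()] or [admm_control()]
#'   matching `solver`; defaults are used when `NULL`.
#' @param ... Passed to [as_multitask_data()] when `data` is a data frame
#'   (`target`, `task`, `features`, `type`).
#' @return An object of class `"tmtl_fit"` with the `p x t` coefficient
#'   matrix `W`, the objective trace, iteration count, convergence flag and
#'   solver diagnostics. Use [tidy()] for coefficients, [glance()] for a
#'   one-row summary, [autoplot()] for convergence/coefficient plots and
#'   [predict()] for new data.
#' @examples
#' sim <- simulate_progression(progression_spec(p = 8, n = rep(40, 3), seed = 2))
#' fit <- tmtl_fit(sim$data, target = y, lambda1 = 0.1, lambda2 = 0.1,
#'                 lambda3 = 0.1, alpha = 0.3)
#' glance(fit)
#' @export
tmtl_fit <- function(data, lambda1, lambda2, lambda3, alpha = 0.3,
                     solver = c("agm", "admm"), control = NULL, ...) {
  solver <- arg_match(solver)
  mtd <- if (inherits(data, "multitask_data")) data else as_multitask_data(data, ...)
  if (solver == "agm") {
    fit_agm(mtd, lambda1, lambda2, lambda3, alpha = alpha,
            control = control %||% agm_control())
  } else {
    fit_admm(mtd, lambda1, lambda2, lambda3, alpha = alpha,
             control = control %||% admm_control())
  }
}

#' @export
print.tmtl_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<tmtl_fit> %s, solver %s\n",
           "  %d features x %d tasks; lambda = (%g, %g, %g), alpha = %g\n",
           "  objective %.6g after %d iteration%s (%sconverged)\n"),
    x$type, x$solver, x$n_features, x$n_tasks,
    x$lambda1, x$lambda2, x$lambda3, x$alpha,
    tail(x$objective, 1), x$n_iter, if (x$n_iter == 1L) "" else "s",
    if (x$converged) "" else "not "
  ))
  invisible(x)
}

#' @export
coef.tmtl_fit <- function(object, ...) object$W

#' Tidy a temporal multi-task fit
#'
#' @param x A `"tmtl_fit"`.
#' @param ... Unused.
#' @return One row per feature/task pair: `feature`, `task`, `estimate`.
#' @exportS3Method generics::tidy
tidy.tmtl_fit <- function(x, ...) {
  tibble::tibble(
    feature = rep(rownames(x$W), times = x$n_tasks),
    task = rep(seq_len(x$n_tasks), each = x$n_features),
    estimate = as.vector(x$W)
  )
}

#' Glance at a temporal multi-task fit
#'
#' @param x A `"tmtl_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: penalties, solver, final objective, iteration
#'   count, convergence flag, and the number of active (nonzero) features.
#' @exportS3Method generics::glance
glance.tmtl_fit <- function(x, ...) {
  tibble::tibble(
    solver = x$solver, type = x$type,
    lambda1 = x$lambda1, lambda2 = x$lambda2, lambda3 = x$lambda3,
    alpha = x$alpha,
    objective = tail(x$objective, 1),
    n_iter = x$n_iter, converged = x$converged,
    n_active = sum(rowSums(abs(x$W)) > 1e-8)
  )
}

#' Predict from a temporal multi-task fit
#'
#' @param object A `"tmtl_fit"`.
#' @param new_data A long-format data frame with the fitted feature columns
#'   and a task column, or a list of per-task design matrices, or a
#'   [multitask_data()].
#' @param task Name of the task column when `new_data` is a data frame.
#' @param ... Unused.
#' @return A tibble with columns `task`, `.pred` (linear predictor for
#'   regression, class in `{-1, +1}` for classification) and, for
#'   classification, `.score` (the linear predictor; ties at 0 predict +1).
#' @export
predict.tmtl_fit <- function(object, new_data, task = "task", ...) {
  xs <- if (inherits(new_data, "multitask_data")) {
    new_data$x
  } else if (is.data.frame(new_data)) {
    levels <- sort(unique(new_data[[task]]))
    if (length(levels) != object$n_tasks) {
      abort(sprintf("`new_data` has %d task levels; the fit has %d.",
                    length(levels), object$n_tasks))
    }
    lapply(levels, function(l) {
      as.matrix(new_data[new_data[[task]] == l, rownames(object$W), drop = FALSE])
    })
  } else if (is.list(new_data)) {
    lapply(new_data, as.matrix)
  } else {
    abort("`new_data` must be a data frame, a list of matrices, or a multitask_data.")
  }
  if (length(xs) != object$n_tasks) {
    abort(sprintf("expected %d per-task matrices, got %d.", object$n_tasks, length(xs)))
  }
  purrr::imap_dfr(xs, function(X, i) {
    if (ncol(X) != object$n_features) {
      abort(sprintf("task %d: %d columns, expected %d.", i, ncol(X), object$n_features))
    }
    score <- drop(X %*% object$W[, i])
    if (object$type == "classification") {
      tibble::tibble(task = i, .pred = ifelse(score >= 0, 1, -1), .score = score)
    } else {
      tibble::tibble(task = i, .pred = score)
    }
  })
}

#' Plot a temporal multi-task fit
#'
#' `type = "trace"` shows the objective against iteration (log-scaled gap
#' to the best value reached); `type = "coefficients"` shows each feature's
#' coefficient profile over time points, the fitted analogue of a
#' progression trajectory.
#'
#' @param object A `"tmtl_fit"`.
#' @param type `"trace"` or `"coefficients"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tmtl_fit <- function(object, type = c("trace", "coefficients"), ...) {
  type <- arg_match(type)
  if (type == "trace") {
    d <- tibble::tibble(iteration = seq_along(object$objective) - 1L,
                        objective = object$objective)
    ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$objective)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "iteration", y = "objective",
                    title = sprintf("%s convergence", toupper(object$solver)))
  } else {
    tidy(object) |>
      ggplot2::ggplot(ggplot2::aes(.data$task, .data$estimate,
                                   group = .data$feature)) +
      ggplot2::geom_line(alpha = 0.6) +
      ggplot2::labs(x = "time point", y = "coefficient",
                    title = "coefficient trajectories")
  }
}
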