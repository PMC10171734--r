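#' Hyperparameter grids for cross-validation
#'
#' The standard search space is log-spaced by decades,
#' `lambda in 10^(-3), ..., 10^4`, for each of the three penalty weights,
#' with `alpha in {0.01, 0.02, 0.05, 0.1, 0.15, ..., 0.5}` (`preset =
#' "paper"`-style full grid; 8^3 x 11 points). Because the full 4-D search
#' is expensive, the default `"coarse"` preset keeps three mid-range values
#' per penalty weight and three values of `alpha`.
#'
#' @param preset `"coarse"` (default) or `"full"`.
#' @param lambda1,lambda2,lambda3,alpha Optional numeric vectors overriding
#'   individual dimensions of the preset.
#' @return A tibble with one row per hyperparameter combination.
#' @export
cv_grid <- function(preset = c("coarse", "full"),
                    lambda1 = NULL, lambda2 = NULL, lambda3 = NULL,
                    alpha = NULL) {
  preset <- arg_match(preset)
  if (preset == "full") {
    lam <- 10^(-3:4)
    alph <- c(0.01, 0.02, 0.05, seq(0.1, 0.5, by = 0.05))
  } else {
    lam <- c(0.01, 0.1, 1)
    alph <- c(0.1, 0.3, 0.5)
  }
  g <- tidyr::expand_grid(
    lambda1 = lambda1 %||% lam,
    lambda2 = lambda2 %||% lam,
    lambda3 = lambda3 %||% lam,
    alpha = alpha %||% alph
  )
  if (nrow(g) == 0L) abort("empty hyperparameter grid.")
  if (any(g$alpha < 0 | g$alpha > 0.5)) abort("`alpha` grid values must lie in [0, 0.5].")
  g
}

#' K-fold cross-validation over the penalty grid
#'
#' Folds are assigned per task (stratified over time points) from `seed`,
#' so every fold holds out samples at every time point and no model is ever
#' scored on samples it was fitted on. The selected combination minimizes
#' mean validation nMSE (regression) or maximizes mean validation accuracy
#' (classification); ties break to the earlier grid row.
#'
#' @inheritParams tmtl_fit
#' @param grid A tibble from [cv_grid()] (or any tibble with columns
#'   `lambda1`, `lambda2`, `lambda3`, `alpha`).
#' @param folds Number of folds `k >= 2`; every task needs at least `k`
#'   samples.
#' @param seed Integer seed for the fold assignment.
#' @param refit If `TRUE` (default), refit on the full data at the selected
#'   combination and attach the fit.
#' @return An object of class `"tmtl_cv"`: `best` (one-row tibble of the
#'   selected combination and its score), `scores` (per-combination,
#'   per-fold table), `metric`, `folds`, `seed`, and `fit` (if refitted).
#' @export
tmtl_cv <- function(data, grid = cv_grid(), folds = 5L, seed = 1L,
                    solver = c("agm", "admm"), control = NULL,
                    refit = TRUE, ...) {
  solver <- arg_match(solver)
  mtd <- if (inherits(data, "multitask_data")) data else as_multitask_data(data, ...)
  check_count(folds, min = 2, what = "folds")
  needed <- c("lambda1", "lambda2", "lambda3", "alpha")
  if (!all(needed %in% names(grid))) {
    abort("`grid` must have columns lambda1, lambda2, lambda3, alpha.")
  }
  if (any(mtd$n_obs < folds)) {
    abort(sprintf("every task needs at least %d samples for %d-fold CV (smallest has %d).",
                  folds, folds, min(mtd$n_obs)))
  }
  metric <- if (mtd$type == "regression") "nmse" else "accuracy"

  fold_ids <- local({
    set.seed(as.integer(seed))
    lapply(mtd$n_obs, function(n) sample(rep_len(seq_len(folds), n)))
  })

  solve_one <- function(l1, l2, l3, a, d) {
    if (solver == "agm") {
      fit_agm(d, l1, l2, l3, alpha = a, control = control %||% agm_control())
    } else {
      fit_admm(d, l1, l2, l3, alpha = a, control = control %||% admm_control())
    }
  }

  score_rows <- purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    g <- grid[gi, ]
    purrr::map_dfr(seq_len(folds), function(f) {
      tr_idx <- lapply(fold_ids, function(id) which(id != f))
      va_idx <- lapply(fold_ids, function(id) which(id == f))
      d_tr <- multitask_data(
        purrr::map2(mtd$x, tr_idx, function(X, j) X[j, , drop = FALSE]),
        purrr::map2(mtd$y, tr_idx, function(y, j) y[j]),
        type = mtd$type
      )
      fit <- solve_one(g$lambda1, g$lambda2, g$lambda3, g$alpha, d_tr)
      xv <- purrr::map2(mtd$x, va_idx, function(X, j) X[j, , drop = FALSE])
      yv <- purrr::map2(mtd$y, va_idx, function(y, j) y[j])
      pred <- lapply(seq_along(xv), function(i) drop(xv[[i]] %*% fit$W[, i]))
      score <- if (metric == "nmse") {
        nmse(yv, pred)
      } else {
        accuracy(yv, lapply(pred, function(s) ifelse(s >= 0, 1, -1)))
      }
      tibble::tibble(grid_row = gi, fold = f,
                     lambda1 = g$lambda1, lambda2 = g$lambda2,
                     lambda3 = g$lambda3, alpha = g$alpha,
                     metric = metric, score = score)
    })
  })

  summary <- score_rows |>
    dplyr::group_by(.data$grid_row, .data$lambda1, .data$lambda2,
                    .data$lambda3, .data$alpha) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$grid_row)
  best_idx <- if (metric == "nmse") {
    which.min(summary$mean_score)
  } else {
    which.max(summary$mean_score)
  }
  best <- summary[best_idx, ]

  fit <- NULL
  if (refit) {
    fit <- solve_one(best$lambda1, best$lambda2, best$lambda3, best$alpha, mtd)
  }
  structure(
    list(best = best, scores = score_rows, metric = metric,
         folds = as.integer(folds), seed = as.integer(seed),
         solver = solver, fit = fit),
    class = "tmtl_cv"
  )
}

#' @export
print.tmtl_cv <- function(x, ...) {
  cat(sprintf(
    "<tmtl_cv> %d-fold, %d grid points, metric %s\n  best: lambda = (%g, %g, %g), alpha = %g, mean %s = %.4g\n",
    x$folds, length(unique(x$scores$grid_row)), x$metric,
    x$best$lambda1, x$best$lambda2, x$best$lambda3, x$best$alpha,
    x$metric, x$best$mean_score
  ))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `"tmtl_cv"`.
#' @param ... Unused.
#' @return The per-combination, per-fold score table.
#' @exportS3Method generics::tidy
tidy.tmtl_cv <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.tmtl_cv <- function(x, ...) {
  dplyr::mutate(x$best, metric = x$metric, folds = x$folds)
}

#' @exportS3Method ggplot2::autoplot
autoplot.tmtl_cv <- function(object, ...) {
  d <- object$scores |>
    dplyr::group_by(.data$grid_row, .data$lambda1) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$grid_row), .data$mean_score)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "grid point", y = paste("mean", object$metric))
}
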