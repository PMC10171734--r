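#' Multi-task (per-time-point) dataset container
#'
#' A progression dataset is a sequence of `t` supervised tasks over a shared
#' feature space: task `i` has an `n_i x p` design matrix and a length-`n_i`
#' target vector. Sample counts may differ across time points (longitudinal
#' attrition). Targets are real for `type = "regression"` and in `{-1, +1}`
#' for `type = "classification"`.
#'
#' @param x List of `t` numeric design matrices, all with `p` columns.
#' @param y List of `t` numeric target vectors, lengths matching `nrow(x[[i]])`.
#' @param type `"regression"` or `"classification"`.
#' @return An object of class `"multitask_data"`: a list with elements `x`,
#'   `y`, `type`, `n_tasks`, `n_features`, `n_obs` (per-task counts) and
#'   `feature_names`.
#' @seealso [as_multitask_data()] to build one from a long-format tibble.
#' @export
multitask_data <- function(x, y, type = c("regression", "classification")) {
  type <- arg_match(type)
  if (!is.list(x) || !is.list(y) || length(x) != length(y) || length(x) < 1L) {
    abort("`x` and `y` must be non-empty lists of equal length (one entry per task).")
  }
  x <- lapply(x, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  y <- lapply(y, function(v) as.double(as.vector(v)))
  p <- ncol(x[[1L]])
  for (i in seq_along(x)) {
    if (ncol(x[[i]]) != p) {
      abort(sprintf("task %d has %d features; expected the shared %d.",
                    i, ncol(x[[i]]), p))
    }
    if (nrow(x[[i]]) != length(y[[i]])) {
      abort(sprintf("task %d: %d rows in `x` but %d targets.",
                    i, nrow(x[[i]]), length(y[[i]])))
    }
    if (nrow(x[[i]]) < 1L) abort(sprintf("task %d has no samples.", i))
    if (anyNA(x[[i]]) || anyNA(y[[i]])) {
      abort(sprintf("task %d contains missing values.", i))
    }
    if (type == "classification" && !all(y[[i]] %in% c(-1, 1))) {
      abort(sprintf(
        "task %d: classification targets must be in {-1, +1} (found %s). Recode 0/1 labels to -1/+1.",
        i, paste(head(setdiff(unique(y[[i]]), c(-1, 1)), 3), collapse = ", ")
      ))
    }
  }
  fn <- colnames(x[[1L]])
  if (is.null(fn)) fn <- paste0("x", seq_len(p))
  structure(
    list(
      x = x, y = y, type = type,
      n_tasks = length(x), n_features = p,
      n_obs = vapply(x, nrow, integer(1)),
      feature_names = fn
    ),
    class = "multitask_data"
  )
}

#' Build a multi-task dataset from a long-format data frame
#'
#' Splits a tibble with one row per sample into the per-time-point task list
#' the solvers consume. The task column defines the temporal order: tasks are
#' sorted by its (unique) values, so integer visit indices or ordered factors
#' both work.
#'
#' @param data A data frame: one row per sample, a task/time-point column,
#'   a target column, and numeric feature columns.
#' @param target Name of the target column (tidy-eval or string).
#' @param task Name of the task (time point) column. Default `"task"`.
#' @param features Optional character vector of feature columns; defaults to
#'   every column other than `target` and `task`.
#' @param type `"regression"` or `"classification"`.
#' @return A [multitask_data()] object.
#' @examples
#' sim <- simulate_progression(progression_spec(p = 5, n = c(30, 25), seed = 1))
#' mtd <- as_multitask_data(sim$data, target = y)
#' mtd$n_obs
#' @export
as_multitask_data <- function(data, target, task = "task", features = NULL,
                              type = c("regression", "classification")) {
  type <- arg_match(type)
  target <- as_name(enquo(target))
  task <- if (is.character(task)) task else as_name(enquo(task))
  stopifnot(is.data.frame(data))
  for (col in c(target, task)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found in `data`.", col))
  }
  if (is.null(features)) features <- setdiff(names(data), c(target, task))
  bad <- features[!vapply(data[features], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric feature column(s): %s", paste(bad, collapse = ", ")))
  }
  levels <- sort(unique(data[[task]]))
  split <- lapply(levels, function(l) data[data[[task]] == l, , drop = FALSE])
  multitask_data(
    x = lapply(split, function(d) as.matrix(d[features])),
    y = lapply(split, function(d) d[[target]]),
    type = type
  )
}

#' @export
print.multitask_data <- function(x, ...) {
  cat(sprintf(
    "<multitask_data> %s: %d task%s, %d features, n = (%s)\n",
    x$type, x$n_tasks, if (x$n_tasks == 1L) "" else "s", x$n_features,
    paste(x$n_obs, collapse = ", ")
  ))
  invisible(x)
}

#' Convert a multi-task dataset back to a long tibble
#'
#' @param x A [multitask_data()] object.
#' @param ... Unused.
#' @return A tibble with columns `task`, `y`, and the feature columns.
#' @exportS3Method tibble::as_tibble
as_tibble.multitask_data <- function(x, ...) {
  purrr::map2_dfr(seq_len(x$n_tasks), seq_len(x$n_tasks), function(i, ...) {
    d <- tibble::as_tibble(as.data.frame(x$x[[i]]))
    names(d) <- x$feature_names
    dplyr::bind_cols(tibble::tibble(task = i, y = x$y[[i]]), d)
  })
}

check_conformable <- function(W, data) {
  if (!is.matrix(W) || nrow(W) != data$n_features || ncol(W) != data$n_tasks) {
    abort(sprintf("`W` must be a %d x %d matrix (features x tasks).",
                  data$n_features, data$n_tasks))
  }
  invisible(W)
}
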