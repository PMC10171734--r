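#' Evaluation metrics for multi-task prediction
#'
#' `nmse()` is the normalized mean squared error used for the regression
#' tasks: per-task squared errors are scaled by the population variance of
#' that task's true targets and pooled over all samples,
#' \deqn{\mathrm{nMSE} = \frac{\sum_i \|y_i - \hat y_i\|_2^2 / \sigma^2(y_i)}
#'   {\sum_i n_i},}
#' with \eqn{\sigma^2(y_i)} the population variance (divide by `n_i`). Under
#' this convention the per-task-mean predictor scores exactly 1 and perfect
#' prediction scores 0. `accuracy()` is the pooled fraction of correct
#' `{-1, +1}` labels across tasks.
#'
#' @param y_true,y_pred Lists of per-task numeric vectors (a single vector
#'   is treated as one task).
#' @return A single number.
#' @examples
#' nmse(list(c(0, 2)), list(c(0, 0)))   # 2
#' accuracy(list(c(1, -1)), list(c(1, 1)))
#' @name metrics
NULL

#' @rdname metrics
#' @export
nmse <- function(y_true, y_pred) {
  if (!is.list(y_true)) y_true <- list(y_true)
  if (!is.list(y_pred)) y_pred <- list(y_pred)
  if (length(y_true) != length(y_pred)) abort("`y_true` and `y_pred` must have the same number of tasks.")
  num <- 0
  n_total <- 0L
  for (i in seq_along(y_true)) {
    yt <- as.numeric(y_true[[i]])
    yp <- as.numeric(y_pred[[i]])
    if (length(yt) != length(yp)) abort(sprintf("task %d: length mismatch.", i))
    n_i <- length(yt)
    v <- mean((yt - mean(yt))^2)   # population variance
    if (v <= 0) {
      abort(sprintf("task %d has zero-variance targets; nMSE is undefined there.", i))
    }
    num <- num + sum((yt - yp)^2) / v
    n_total <- n_total + n_i
  }
  num / n_total
}

#' @rdname metrics
#' @export
accuracy <- function(y_true, y_pred) {
  if (!is.list(y_true)) y_true <- list(y_true)
  if (!is.list(y_pred)) y_pred <- list(y_pred)
  if (length(y_true) != length(y_pred)) abort("`y_true` and `y_pred` must have the same number of tasks.")
  yt <- unlist(y_true)
  yp <- unlist(y_pred)
  if (length(yt) != length(yp)) abort("pooled label vectors differ in length.")
  if (!all(c(yt, yp) %in% c(-1, 1))) abort("labels must be in {-1, +1}.")
  mean(yt == yp)
}
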