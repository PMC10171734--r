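#' Write a multi-task dataset as per-task CSV files plus a manifest
#'
#' One CSV per time point (mirroring how longitudinal cohorts distribute
#' one visit per file) with a header row, a target column, and the shared
#' feature columns; plus a JSON manifest recording the file order (which
#' defines the temporal order), the target column and the task type.
#'
#' @param data A [multitask_data()].
#' @param dir Output directory (created if needed).
#' @param target Name for the target column in the files.
#' @return The manifest path, invisibly.
#' @export
write_multitask_data <- function(data, dir, target = "y") {
  stopifnot(inherits(data, "multitask_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(data$n_tasks)
  for (i in seq_len(data$n_tasks)) {
    d <- tibble::as_tibble(as.data.frame(data$x[[i]]))
    names(d) <- data$feature_names
    d[[target]] <- data$y[[i]]
    files[i] <- sprintf("task_%02d.csv", i)
    readr::write_csv(d, file.path(dir, files[i]))
  }
  manifest <- list(task_files = files, target_column = target,
                   feature_columns = data$feature_names,
                   task_type = data$type, delimiter = ",")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a multi-task dataset from a manifest
#'
#' Loads the per-task files named by a JSON manifest (see
#' [write_multitask_data()]) in manifest order, realigns feature columns by
#' name, and validates the shared feature set and (for classification) the
#' `{-1, +1}` label domain.
#'
#' @param manifest Path to the manifest JSON file.
#' @param standardize If `TRUE`, center and scale each feature using
#'   statistics pooled over all tasks of this dataset; the centers and
#'   scales are attached as attributes so held-out data can be transformed
#'   with training statistics only.
#' @return A [multitask_data()] (with `center`/`scale` attributes when
#'   standardized).
#' @export
read_multitask_manifest <- function(manifest, standardize = FALSE) {
  if (!file.exists(manifest)) abort(sprintf("manifest not found: %s", manifest))
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  feats <- m$feature_columns
  xs <- vector("list", length(m$task_files))
  ys <- vector("list", length(m$task_files))
  for (i in seq_along(m$task_files)) {
    path <- file.path(dir, m$task_files[i])
    if (!file.exists(path)) abort(sprintf("task file not found: %s", path))
    d <- readr::read_csv(path, show_col_types = FALSE)
    if (!m$target_column %in% names(d)) {
      abort(sprintf("%s: missing target column `%s`.", m$task_files[i], m$target_column))
    }
    missing <- setdiff(feats, names(d))
    if (length(missing)) {
      abort(sprintf("%s: missing feature column(s) %s.",
                    m$task_files[i], paste(missing, collapse = ", ")))
    }
    bad <- feats[!vapply(d[feats], is.numeric, logical(1))]
    if (length(bad)) {
      abort(sprintf("%s: non-numeric feature column(s) %s.",
                    m$task_files[i], paste(bad, collapse = ", ")))
    }
    xs[[i]] <- as.matrix(d[feats])   # realigned by name to manifest order
    ys[[i]] <- d[[m$target_column]]
  }
  out <- multitask_data(xs, ys, type = m$task_type)
  if (standardize) {
    pooled <- do.call(rbind, out$x)
    ctr <- colMeans(pooled)
    scl <- apply(pooled, 2, sd)
    scl[scl == 0] <- 1
    out$x <- lapply(out$x, function(X) scale(X, center = ctr, scale = scl)[, , drop = FALSE])
    attr(out, "center") <- ctr
    attr(out, "scale") <- scl
  }
  out
}

#' Write a fit result to disk
#'
#' Writes the coefficient matrix as headered CSV (features x tasks), a JSON
#' run record (penalties, solver, objective trace, diagnostics, convergence
#' flag) sufficient to reproduce the run, and a short plain-text log.
#'
#' @param fit A `"tmtl_fit"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fit_result <- function(fit, dir) {
  stopifnot(inherits(fit, "tmtl_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w_path <- file.path(dir, "coefficients.csv")
  d <- tibble::as_tibble(as.data.frame(fit$W), rownames = "feature")
  readr::write_csv(d, w_path)
  record <- list(
    solver = fit$solver, type = fit$type,
    lambda1 = fit$lambda1, lambda2 = fit$lambda2, lambda3 = fit$lambda3,
    alpha = fit$alpha,
    n_features = fit$n_features, n_tasks = fit$n_tasks, n_obs = fit$n_obs,
    n_iter = fit$n_iter, converged = fit$converged,
    objective_trace = fit$objective,
    diagnostics = fit$diagnostics[setdiff(names(fit$diagnostics), "control")],
    control = fit$diagnostics$control
  )
  r_path <- file.path(dir, "run_record.json")
  jsonlite::write_json(record, r_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  l_path <- file.path(dir, "run.log")
  writeLines(c(
    sprintf("solver=%s type=%s", fit$solver, fit$type),
    sprintf("lambda=(%g,%g,%g) alpha=%g", fit$lambda1, fit$lambda2, fit$lambda3, fit$alpha),
    sprintf("iterations=%d converged=%s final_objective=%.10g",
            fit$n_iter, fit$converged, tail(fit$objective, 1))
  ), l_path)
  invisible(c(coefficients = w_path, record = r_path, log = l_path))
}

#' Read a coefficient matrix written by [write_fit_result()]
#'
#' @param path Path to `coefficients.csv`.
#' @return A numeric matrix with feature row names.
#' @export
read_coefficients <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  W <- as.matrix(d[setdiff(names(d), "feature")])
  rownames(W) <- d$feature
  W
}
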