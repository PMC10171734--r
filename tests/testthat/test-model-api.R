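test_that("the tidy front door dispatches and both solvers agree", {
  sim <- simulate_progression(progression_spec(p = 5, n = c(30, 25, 25),
                                               s_shared = 3, seed = 51))
  fa <- tmtl_fit(sim$data, target = y, lambda1 = 0.1, lambda2 = 0.1,
                 lambda3 = 0.1, alpha = 0.3, solver = "agm",
                 control = agm_control(tol = 1e-10, max_iter = 50000))
  fd <- tmtl_fit(sim$data, target = y, lambda1 = 0.1, lambda2 = 0.1,
                 lambda3 = 0.1, alpha = 0.3, solver = "admm",
                 control = admm_control(tol_primal = 1e-6, tol_dual = 1e-6,
                                        max_iter = 20000))
  expect_lt(abs(tail(fa$objective, 1) - tail(fd$objective, 1)) /
              tail(fa$objective, 1), 1e-3)
  expect_error(tmtl_fit(sim$data, target = y, lambda1 = 0.1, lambda2 = 0.1,
                        lambda3 = 0.1, solver = "newton"), "agm")
  # refit determinism (bit-for-bit for the accelerated solver)
  fa2 <- tmtl_fit(sim$data, target = y, lambda1 = 0.1, lambda2 = 0.1,
                  lambda3 = 0.1, alpha = 0.3, solver = "agm",
                  control = agm_control(tol = 1e-10, max_iter = 50000))
  expect_identical(fa$W, fa2$W)
  # tidy/glance accessors
  td <- tidy(fa)
  expect_equal(nrow(td), 5 * 3)
  expect_named(td, c("feature", "task", "estimate"))
  expect_equal(glance(fa)$converged, TRUE)
})

test_that("predictions follow the per-task linear model", {
  sim <- simulate_progression(progression_spec(p = 4, n = c(30, 30),
                                               s_shared = 2, noise_sd = 0,
                                               seed = 52))
  f <- tmtl_fit(sim$mtd, lambda1 = 0, lambda2 = 0, lambda3 = 0, alpha = 0,
                control = agm_control(tol = 1e-13, max_iter = 50000))
  pred <- predict(f, sim$mtd)
  expect_equal(pred$.pred, unlist(sim$mtd$y), tolerance = 1e-5)
  # zero fit: zero predictions for regression, ties to +1 for classification
  f$W[] <- 0
  expect_true(all(predict(f, sim$mtd)$.pred == 0))
  xs <- list(matrix(0, 3, 2)); ys <- list(c(1, -1, 1))
  dc <- multitask_data(xs, ys, type = "classification")
  fc <- fit_agm(dc, 10, 0, 0, alpha = 0, control = agm_control(max_iter = 10))
  predc <- predict(fc, dc)
  expect_true(all(predc$.pred == 1))
  expect_error(predict(f, list(matrix(0, 2, 9), matrix(0, 2, 9))), "columns")
})

test_that("nMSE follows the pooled variance-normalized convention", {
  expect_equal(nmse(list(c(0, 2)), list(c(0, 0))), 2)
  set.seed(53)
  ys <- lapply(c(7, 11), function(n) rnorm(n, sd = 2))
  expect_equal(nmse(ys, ys), 0)
  # per-task mean predictor scores exactly 1
  means <- lapply(ys, function(y) rep(mean(y), length(y)))
  expect_equal(nmse(ys, means), 1, tolerance = 1e-12)
  expect_error(nmse(list(rep(1, 4)), list(rep(0, 4))), "zero-variance")
  expect_error(nmse(list(1:3), list(1:2)), "length")
})

test_that("accuracy pools tasks and guards its label domain", {
  expect_equal(accuracy(list(c(1, -1, 1)), list(c(1, -1, 1))), 1)
  expect_equal(accuracy(list(c(1, -1)), list(c(-1, 1))), 0)
  expect_equal(accuracy(list(rep(1, 6), rep(-1, 4)), list(c(rep(1, 3), rep(-1, 3)), c(rep(-1, 2), rep(1, 2)))), 0.5)
  expect_error(accuracy(list(c(0, 1)), list(c(1, 1))), "labels")
})

test_that("cross-validation selects on held-out data only", {
  sim <- simulate_progression(progression_spec(p = 6, n = c(40, 40),
                                               s_shared = 3, noise_sd = 0,
                                               seed = 54))
  # single-point grid: returns that point
  g1 <- cv_grid(lambda1 = 0.01, lambda2 = 0.01, lambda3 = 0.01, alpha = 0.2)
  cv1 <- tmtl_cv(sim$mtd, grid = g1, folds = 3, seed = 5,
                 control = agm_control(tol = 1e-8, max_iter = 20000))
  expect_equal(nrow(cv1$best), 1)
  expect_equal(cv1$best$alpha, 0.2)
  # noiseless data: near-zero validation error at small penalties
  expect_lt(cv1$best$mean_score, 0.05)
  # fold disjointness: reconstruct the assignment and check the partition
  set.seed(cv1$seed)
  ids <- lapply(sim$mtd$n_obs, function(n) sample(rep_len(seq_len(3), n)))
  for (i in seq_along(ids)) {
    for (f in 1:3) {
      expect_length(intersect(which(ids[[i]] == f), which(ids[[i]] != f)), 0)
    }
    expect_setequal(unlist(lapply(1:3, function(f) which(ids[[i]] == f))),
                    seq_len(sim$mtd$n_obs[i]))
  }
  expect_error(tmtl_cv(sim$mtd, grid = g1, folds = 1), "integer")
  small <- multitask_data(list(matrix(rnorm(6), 3, 2)), list(rnorm(3)))
  expect_error(tmtl_cv(small, grid = g1, folds = 5), "at least 5")
})

test_that("selected weights are stable across fold seeds on separable data", {
  sim <- simulate_progression(progression_spec(p = 6, n = c(60, 60),
                                               s_shared = 2, noise_sd = 0.05,
                                               seed = 55))
  g <- cv_grid(lambda1 = c(0.01, 10), lambda2 = 0.01, lambda3 = 0.01,
               alpha = 0.2)
  picks <- vapply(1:3, function(s) {
    cv <- tmtl_cv(sim$mtd, grid = g, folds = 3, seed = s, refit = FALSE,
                  control = agm_control(tol = 1e-6, max_iter = 5000))
    cv$best$lambda1
  }, numeric(1))
  expect_equal(length(unique(picks)), 1L)
})
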