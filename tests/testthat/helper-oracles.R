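# Independent oracles used across the test suite. None of these share code
# paths with the package: the row prox is solved through its DUAL (a smooth
# box/ball-constrained quadratic, by accelerated projected gradient), the
# full objective by derivative-free minimization, and baselines in closed
# form.

# Solves min_q 0.5||q - v||^2 + lam1||q||_1 + lam2||q||_2 + lam3 sum|q_j - q_{j+1}|
# via its dual: q* = v - a - b - D'c with |a_j| <= lam1, ||b||_2 <= lam2,
# |c_j| <= lam3, minimizing 0.5||v - a - b - D'c||^2.
oracle_row_prox <- function(v, lam1, lam2, lam3, iters = 20000) {
  n <- length(v)
  D <- if (n >= 2) diff(diag(n)) else matrix(0, 0, n)
  a <- numeric(n); b <- numeric(n); cc <- numeric(nrow(D))
  za <- a; zb <- b; zc <- cc
  t_prev <- 1
  L <- 6  # spectral bound of the stacked operator [I I D']' [I I D']
  proj <- function(a, b, cc) {
    a <- pmin(pmax(a, -lam1), lam1)
    nb <- sqrt(sum(b^2))
    if (nb > lam2) b <- b * (lam2 / nb)
    cc <- pmin(pmax(cc, -lam3), lam3)
    list(a = a, b = b, cc = cc)
  }
  for (k in seq_len(iters)) {
    r <- v - za - zb - if (n >= 2) drop(crossprod(D, zc)) else 0
    pa <- proj(za + r / L, zb + r / L, if (n >= 2) zc + drop(D %*% r) / L else zc)
    t_new <- (1 + sqrt(1 + 4 * t_prev^2)) / 2
    m <- (t_prev - 1) / t_new
    za <- pa$a + m * (pa$a - a); zb <- pa$b + m * (pa$b - b); zc <- pa$cc + m * (pa$cc - cc)
    a <- pa$a; b <- pa$b; cc <- pa$cc
    t_prev <- t_new
    # optimality is judged by the gradient mapping at the ACCEPTED point:
    # momentum can park the iterate on a constraint face while the true
    # solution is interior, so iterate stagnation is not a valid stop
    r0 <- v - a - b - if (n >= 2) drop(crossprod(D, cc)) else 0
    p0 <- proj(a + r0 / L, b + r0 / L, if (n >= 2) cc + drop(D %*% r0) / L else cc)
    gm <- max(abs(p0$a - a), abs(p0$b - b), if (length(cc)) abs(p0$cc - cc) else 0)
    if (gm < 1e-13) break
    if (k %% 1000 == 0) {
      # periodic momentum restart keeps the extrapolation honest
      za <- a; zb <- b; zc <- cc; t_prev <- 1
    }
  }
  v - a - b - if (n >= 2) drop(crossprod(D, cc)) else 0
}

row_prox_objective <- function(q, v, lam1, lam2, lam3) {
  0.5 * sum((q - v)^2) + lam1 * sum(abs(q)) + lam2 * sqrt(sum(q^2)) +
    (if (length(q) >= 2) lam3 * sum(abs(diff(q))) else 0)
}

# Full-program oracle on tiny instances: derivative-free minimization of the
# nonsmooth objective over vec(W), multiple starts, best value kept.
oracle_objective_min <- function(data, ts, lam1, lam2, lam3, restarts = 4) {
  p <- data$n_features; nt <- data$n_tasks
  fn <- function(w) objective_value(matrix(w, p, nt), data, ts, lam1, lam2, lam3)
  starts <- list(rep(0, p * nt), as.vector(least_squares_W(data)))
  set.seed(73)
  for (r in seq_len(restarts)) starts[[length(starts) + 1]] <- rnorm(p * nt, sd = 0.5)
  best <- Inf
  for (s in starts) {
    res <- optim(s, fn, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-14))
    res <- optim(res$par, fn, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-14))
    best <- min(best, res$value)
  }
  best
}

least_squares_W <- function(data) {
  vapply(seq_len(data$n_tasks),
         function(i) qr.solve(data$x[[i]], data$y[[i]]),
         numeric(data$n_features))
}

# Independently coded sparse group Lasso on W itself (no temporal structure,
# no acceleration): plain proximal gradient with soft-threshold-then-group
# shrink per row, run long.
oracle_sgl_fit <- function(data, lam1, lam2, iters = 30000, tol = 1e-12) {
  p <- data$n_features; nt <- data$n_tasks
  L <- max(vapply(data$x, function(X) svd(X, nu = 0, nv = 0)$d[1]^2, numeric(1)))
  W <- matrix(0, p, nt)
  obj_prev <- Inf
  for (k in seq_len(iters)) {
    G <- W * 0
    for (i in seq_len(nt)) {
      G[, i] <- crossprod(data$x[[i]], data$x[[i]] %*% W[, i] - data$y[[i]])
    }
    V <- W - G / L
    for (r in seq_len(p)) {
      u <- sign(V[r, ]) * pmax(abs(V[r, ]) - lam1 / L, 0)
      nu <- sqrt(sum(u^2))
      W[r, ] <- if (nu > 0) max(nu - lam2 / L, 0) / nu * u else u
    }
    obj <- sum(vapply(seq_len(nt), function(i)
      0.5 * sum((data$x[[i]] %*% W[, i] - data$y[[i]])^2), numeric(1))) +
      lam1 * sum(abs(W)) + lam2 * sum(sqrt(rowSums(W^2)))
    if (abs(obj_prev - obj) < tol * max(1, abs(obj))) break
    obj_prev <- obj
  }
  W
}

# Per-task ridge with closed-form solves and per-task lambda chosen by the
# shared fold assignment; the matched-regularization baseline.
ridge_baseline <- function(data, fold_ids, lambdas = 10^seq(-2, 2, by = 0.5)) {
  folds <- max(fold_ids[[1]])
  W <- matrix(0, data$n_features, data$n_tasks)
  for (i in seq_len(data$n_tasks)) {
    X <- data$x[[i]]; y <- data$y[[i]]
    errs <- vapply(lambdas, function(l) {
      e <- 0
      for (f in seq_len(folds)) {
        tr <- fold_ids[[i]] != f
        w <- solve(crossprod(X[tr, , drop = FALSE]) + l * diag(ncol(X)),
                   crossprod(X[tr, , drop = FALSE], y[tr]))
        e <- e + sum((X[!tr, , drop = FALSE] %*% w - y[!tr])^2)
      }
      e
    }, numeric(1))
    l_best <- lambdas[which.min(errs)]
    W[, i] <- solve(crossprod(X) + l_best * diag(ncol(X)), crossprod(X, y))
  }
  W
}

support_f1 <- function(W_hat, support_true, rel_threshold = 0.1) {
  rn <- sqrt(rowSums(W_hat^2))
  est <- rn > rel_threshold * max(rn)
  tp <- sum(est & support_true)
  if (tp == 0) return(0)
  2 * tp / (sum(est) + sum(support_true))
}

random_regression_instance <- function(p, nt, n, seed, sd_w = 1) {
  set.seed(seed)
  xs <- lapply(seq_len(nt), function(i) matrix(rnorm(n * p), n, p))
  W <- matrix(rnorm(p * nt, sd = sd_w), p, nt)
  ys <- lapply(seq_len(nt), function(i) drop(xs[[i]] %*% W[, i]) + rnorm(n, sd = 0.3))
  multitask_data(xs, ys, type = "regression")
}
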