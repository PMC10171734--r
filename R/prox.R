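#' Proximal operators for the composite temporal penalty
#'
#' The solvers repeatedly evaluate the proximal operator
#' \deqn{\pi(v) = \arg\min_q \tfrac12\|q - v\|_2^2 + \lambda_1\|q\|_1 +
#'   \lambda_2\|q\|_2 + \lambda_3\sum_j |q_j - q_{j+1}|}
#' over each length-`t` coefficient row. This composite prox decomposes
#' exactly: first the fused-Lasso prox (total variation then elementwise
#' soft-threshold), then group (L2) shrinkage. The functions here are the
#' building blocks of that chain; each is a prox in its own right.
#'
#' `prox_soft_threshold()` minimizes `0.5*||q - v||^2 + lam*||q||_1`
#' (elementwise shrink toward zero). `prox_group()` minimizes
#' `0.5*||q - v||^2 + lam*||q||_2` (shrink the whole vector's norm; the zero
#' vector maps to zero). `prox_sparse_group()` composes the two,
#' soft-threshold first. `prox_tv()` is the exact 1-D total-variation prox.
#' `prox_fused_lasso()` is TV then soft-threshold — the order matters and is
#' the direction in which the composition is exact. `prox_fused_sparse_group()`
#' applies the full three-penalty row prox, and `prox_matrix_rows()` maps it
#' over the rows of a matrix (rows are decoupled in the matrix problem).
#'
#' @param v Numeric vector (a coefficient row across time points).
#' @param lam,lam1,lam2,lam3 Non-negative penalty weights: `lam1` the L1
#'   (lasso) weight, `lam2` the L2 (group) weight, `lam3` the fusion
#'   (total-variation) weight.
#' @return A numeric vector of the same length as `v` (or a matrix of the
#'   same shape for `prox_matrix_rows()`).
#' @name prox
#' @examples
#' prox_soft_threshold(c(3, -1, 0.2), 1)
#' prox_group(c(3, 4), 2.5)
#' prox_fused_lasso(c(1, 3), lam1 = 0.5, lam3 = 1)
NULL

#' @rdname prox
#' @export
prox_soft_threshold <- function(v, lam) {
  check_nonneg(lam, "lam")
  sign(v) * pmax(abs(v) - lam, 0)
}

#' @rdname prox
#' @export
prox_group <- function(v, lam) {
  check_nonneg(lam, "lam")
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(v * 0)
  max(nv - lam, 0) / nv * v
}

#' @rdname prox
#' @export
prox_sparse_group <- function(v, lam1, lam2) {
  prox_group(prox_soft_threshold(v, lam1), lam2)
}

#' @rdname prox
#' @export
prox_tv <- function(v, lam) {
  check_nonneg(lam, "lam")
  n <- length(v)
  if (n <= 1L || lam == 0) return(v)
  tv_condat(as.double(v), as.double(lam))
}

# Direct (non-iterative) 1-D total-variation prox: maintains running lower
# and upper bounds on the taut string, fusing segments as it scans and
# emitting a segment whenever the string is forced to jump. Exact for every
# input; O(n) in practice.
tv_condat <- function(y, lam) {
  n <- length(y)
  x <- numeric(n)
  k <- 1L; k0 <- 1L; km <- 1L; kp <- 1L
  umin <- lam; umax <- -lam
  vmin <- y[1L] - lam; vmax <- y[1L] + lam
  repeat {
    while (k == n) {
      if (umin < 0) {
        # the string leaves the segment downward: fix the segment at vmin
        repeat { x[k0] <- vmin; k0 <- k0 + 1L; if (k0 > km) break }
        k <- km <- k0
        vmin <- y[k]
        umin <- lam
        umax <- y[k] + lam - vmax
      } else if (umax > 0) {
        repeat { x[k0] <- vmax; k0 <- k0 + 1L; if (k0 > kp) break }
        k <- kp <- k0
        vmax <- y[k]
        umax <- -lam
        umin <- y[k] - lam - vmin
      } else {
        # string can run straight to the end
        vmin <- vmin + umin / (k - k0 + 1)
        repeat { x[k0] <- vmin; k0 <- k0 + 1L; if (k0 > n) break }
        return(x)
      }
    }
    umin <- umin + y[k + 1L] - vmin
    if (umin < -lam) {
      # lower bound violated: negative jump at km, restart a segment after it
      repeat { x[k0] <- vmin; k0 <- k0 + 1L; if (k0 > km) break }
      k <- km <- kp <- k0
      vmin <- y[k]
      vmax <- y[k] + 2 * lam
      umin <- lam
      umax <- -lam
    } else {
      umax <- umax + y[k + 1L] - vmax
      if (umax > lam) {
        repeat { x[k0] <- vmax; k0 <- k0 + 1L; if (k0 > kp) break }
        k <- km <- kp <- k0
        vmax <- y[k]
        vmin <- y[k] - 2 * lam
        umin <- lam
        umax <- -lam
      } else {
        k <- k + 1L
        if (umin >= lam) {
          vmin <- vmin + (umin - lam) / (k - k0 + 1)
          umin <- lam
          km <- k
        }
        if (umax <= -lam) {
          vmax <- vmax + (umax + lam) / (k - k0 + 1)
          umax <- -lam
          kp <- k
        }
      }
    }
  }
}

#' @rdname prox
#' @export
prox_fused_lasso <- function(v, lam1, lam3) {
  check_nonneg(lam1, "lam1")
  check_nonneg(lam3, "lam3")
  prox_soft_threshold(prox_tv(v, lam3), lam1)
}

#' @rdname prox
#' @export
prox_fused_sparse_group <- function(v, lam1, lam2, lam3) {
  prox_group(prox_fused_lasso(v, lam1, lam3), lam2)
}

#' @rdname prox
#' @param V Numeric matrix (features x time points).
#' @export
prox_matrix_rows <- function(V, lam1, lam2, lam3) {
  check_nonneg(lam1, "lam1")
  check_nonneg(lam2, "lam2")
  check_nonneg(lam3, "lam3")
  stopifnot(is.matrix(V))
  out <- V
  for (i in seq_len(nrow(V))) {
    out[i, ] <- prox_fused_sparse_group(V[i, ], lam1, lam2, lam3)
  }
  out
}
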