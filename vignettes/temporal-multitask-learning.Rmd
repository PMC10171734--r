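---
title: "Temporal multi-task learning: model, solvers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal multi-task learning: model, solvers and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtl)
```

## The problem

In a progression study — cognitive decline, symptom trajectories, epidemic
counts — the same feature set predicts an outcome at each of $t$ ordered
time points, with sample counts typically shrinking over time as
participants drop out. Fitting each time point separately ignores that the
underlying process evolves continuously; pooling everything into one model
ignores that it evolves at all. `tmtl` treats each time point as a task
over a shared feature space and couples the tasks three ways: through a
global temporal structure that mixes each task's coefficients with its
entire history, through joint feature selection, and through a penalty on
how fast coefficients may change between consecutive time points.

## The model

Let $W \in \mathbb{R}^{p \times t}$ hold one coefficient column per time
point. The *temporal tasks* are defined recursively:
$\bar\omega_1 = w_1$ and
$\bar\omega_i = \alpha\,\bar\omega_{i-1} + (1-\alpha)\,w_i$, with
$\alpha \in [0, 0.5]$ the relational degree between a time point and its
accumulated history. Stacking them column-wise gives $W R(\alpha)$, where
$R(\alpha)$ is upper triangular, invertible, and has columns that are
convex weights decaying with temporal distance
(`agts_matrix()`, `agts_column_weights()`). The cap at $0.5$ encodes that
the current state matters at least as much as the entire past; $\alpha$
itself is chosen by cross-validation, so the strength of temporal coupling
adapts to the data.

The estimator solves the convex program

$$\min_W \; \mathcal{L}(W)
  + \lambda_1 \lVert WR \rVert_1
  + \lambda_2 \lVert WR \rVert_{1,2}
  + \lambda_3 \lVert (WRH)^\top \rVert_1,$$

where $\mathcal{L}$ is $\tfrac12\sum_i \lVert X_i w_i - y_i \rVert_2^2$
for regression or the per-task-averaged logistic loss
$\sum_i \tfrac{1}{n_i}\sum_j \log(1 + e^{-y_{ij} x_{ij}^\top w_i})$ for
$\{-1,+1\}$ labels. The first two penalties form a *temporal sparse group
Lasso*: the L1 term sparsifies individual temporal-task coefficients, and
the $\lVert\cdot\rVert_{1,2}$ term (sum over features of the L2 norm of
the feature's row of $WR$) removes whole features from every time point at
once. The third term is a fused Lasso on consecutive differences of the
temporal tasks — $H$ is the $t \times (t-1)$ difference operator — which
makes the fitted trajectories piecewise-constant-ish rather than noisy.

Two conventions to be aware of when transferring penalty weights from
other software: the squared loss carries a factor $\tfrac12$, and the
logistic loss is averaged within each task. Both solvers use the same
conventions, so $\lambda$ values are interchangeable between them.

## Two solvers

**Accelerated proximal gradient (`fit_agm()`, the default).** Because
$R$ is invertible, substituting $Q = WR$ turns the program into a smooth
loss of $Q R^{-1}$ plus a penalty whose rows decouple. The row-wise
proximal operator has an exact two-stage decomposition: a 1-D
total-variation prox (solved by a direct, non-iterative taut-string scan —
exact for every input, chosen over iterative schemes because $t$ is small
and exactness keeps the decomposition testable), then elementwise
soft-thresholding, then group shrinkage. The order matters: TV first, then
soft-threshold, then group — the reverse compositions are *not* the prox
of the summed penalty, and the test suite checks both that the implemented
order matches a dual-oracle solution and that the reverse order differs.
Momentum follows the standard $t_i = \tfrac12(1 + \sqrt{4t_{i-1}^2+1})$
schedule. The step size starts from the spectral bound
$\sigma_X^2\,\sigma_{\max}(R^{-1})^2$ — the loss-gradient constant
$\sigma_X^2$ (largest per-task design singular value, squared) corrected
for the change of variables — and is backtracked by doubling until the
quadratic upper bound holds.

We use the *monotone* variant of the accelerated scheme: the prox
candidate drives the momentum sequence, but the reported iterate keeps the
previous point whenever the candidate would increase the objective. Plain
accelerated gradient is not monotone, and a non-increasing objective trace
is both easier to reason about and what the convergence monitor (relative
objective change below `tol`, default `1e-4`) assumes. An absolute-change
monitor is available via `agm_control(monitor = "absolute")`.

**Inexact ADMM (`fit_admm()`).** The constraints $A = WR$ (one auxiliary
matrix carries both sparsity penalties) and $B = WRH$ split the program.
The $W$ block under the squared loss is linearized per task — Jacobi
style, all other columns held at their previous iterate — so each column
solves a fixed linear system $V_i w_i = q_i$ with
$V_i = X_i^\top X_i + \rho(1 + M_{ii}) I$, factorized once per fit by
Cholesky. The extra $\rho I$ in $V_i$ is a proximal damping term, and its
anchor $+\rho\,w_i^{(k)}$ appears in $q_i$; without the anchor the
iteration's fixed point acquires a spurious $\rho w$ term and stops being
the minimizer of the augmented Lagrangian — the test suite verifies the
implemented update's fixed point against a directly solved stacked linear
system. Under the logistic loss, the $W$ block is minimized by L-BFGS with
the analytic gradient (inner cap 50 iterations, tolerance `1e-6`). The
$A$ update is the row-wise sparse-group prox, the $B$ update elementwise
soft-thresholding, duals ascend at rate $\rho$, and iteration stops when
both the primal residual $\lVert WR - A\rVert_F + \lVert WRH - B\rVert_F$
and the dual residual $\lVert \rho\,\Delta A + \rho\,\Delta B H^\top
\rVert_F$ drop below `1e-4` (absolute; the textbook dual residual would
carry an extra $R^\top$ factor on the $\Delta A$ term — we keep the
simpler unweighted form, which only rescales the stopping surface). The
fixed point does not depend on $\rho$; speed does, so
$\rho \in \{0.01, 0.1, 1, 2.5, 5\}$ is worth sweeping when iteration
counts matter. Default $\rho = 1$; all variables start at zero, as does
the accelerated solver — the conventional sparse-regression start.

Both solvers are deterministic: identical inputs produce bit-identical
traces. On shared instances they agree to well below $10^{-3}$ relative in
objective (convexity guarantees a common minimum), which the acceptance
checks recompute on fresh random instances.

## Tuning parameters

| parameter | meaning | default / grid |
|---|---|---|
| `lambda1` | L1 weight on $WR$ (within-task sparsity) | grid $10^{-3},\dots,10^{4}$ by decades (full), $\{0.01, 0.1, 1\}$ (coarse) |
| `lambda2` | group weight (feature in/out across all time points) | same |
| `lambda3` | fusion weight (temporal smoothness) | same |
| `alpha`   | history weight in $[0, 0.5]$; 0 decouples tasks | $\{0.01, 0.02, 0.05, 0.1, \dots, 0.5\}$ (full), $\{0.1, 0.3, 0.5\}$ (coarse) |

`tmtl_cv()` runs $k$-fold cross-validation (default $k = 5$) with folds
assigned per task from a seed, selecting by mean validation nMSE
(regression) or accuracy (classification). The coarse preset exists
because the full grid is $8^3 \times 11$ points; a realistic workflow is
coarse first, then a refined grid around the winner.

Useful degenerate corners, all verified in the tests: all
$\lambda = 0$ recovers per-task least squares; $\alpha = 0,
\lambda_3 = 0$ is exactly a sparse group Lasso on $W$; $\lambda_1$ above
$\max_i \lVert X_i^\top y_i \rVert_\infty$ zeroes the fit.

## Evaluation

`nmse()` implements the pooled, variance-normalized squared error
$\bigl[\sum_i \lVert y_i - \hat y_i\rVert^2 / \sigma^2(y_i)\bigr] /
\sum_i n_i$ with $\sigma^2$ the *population* variance of the true test
targets. That convention is chosen so two identities hold exactly: the
per-task-mean predictor scores 1 and perfect prediction scores 0 — both
asserted in the tests to machine precision. Tasks with zero target
variance are rejected rather than silently scored. `accuracy()` pools
correct $\{-1,+1\}$ labels over all tasks; a score of exactly zero
predicts $+1$ (an arbitrary documented tie-break).

## The synthetic cohort generator

`simulate_progression()` emulates the regime the method is designed for:
i.i.d. standard-normal designs over $p$ shared features; per-time-point
sample counts that shrink over time (default `(120, 110, 100, 90, 60,
50)`, a typical attrition profile at reduced scale, chosen to exercise the
unequal-$n_i$ code paths); a small shared support whose coefficients
follow a smooth random walk across columns (`smooth_step` scales the
drift); optional single-task features; Gaussian noise for regression and
logistic sampling for classification — logistic rather than
label-flipping, so the generated labels match the loss the solvers
optimize. Everything is reproducible from one seed.

What the generator does *not* emulate: correlated or heavy-tailed
features, missing visits within a participant, informative dropout, or
measurement batch effects. Passing recovery checks on this generator
therefore demonstrates the estimator's correctness and its advantage over
per-task baselines under the model's own assumptions, not robustness to
real-cohort pathologies.

## Problem sizes used in the checks

The recovery study in the acceptance checks uses $p = 30$, $t = 5$,
$n_i = 100$, six shared support rows, drift 0.1, noise 0.5, over ten
generator seeds; model selection is the coarse grid with five folds
(CV fits at `tol = 1e-3`, capped at 400 iterations, final fit at
`tol = 1e-5`), against a per-task ridge baseline whose penalty is chosen
by the same folds. A feature counts as recovered when its coefficient row
norm exceeds 10% of the largest row norm — the standard relative rule for
declaring an active set in sparse recovery. Oracle comparisons for the
proximal operators use an accelerated projected-gradient solver of the
*dual* problem (a box/ball-constrained quadratic), an independent code
path that never touches the decomposition being tested; whole-program
oracles on tiny instances use restarted derivative-free minimization.

## Numerical choices and edge cases

- `alpha` outside $[0, 0.5]$, negative penalty weights, non-$\{-1,+1\}$
  labels, and shape mismatches are rejected with explicit errors.
- $t = 1$: no differences exist, so $H$ is a $1 \times 0$ matrix and the
  fusion penalty vanishes; the fused prox falls back to soft-thresholding.
- The group prox maps the zero vector to zero (the
  subdifferential-consistent choice).
- $R^{-1}$ is computed once per fit by triangular back-substitution
  (`backsolve`), never by generic inversion, and cached in the
  `temporal_structure` object.
- CV ties break to the earlier grid row; classification score ties
  predict $+1$.
- The logistic loss uses `log1p`-based evaluation, stable for margins of
  either sign at any magnitude.

## Known limitations

A single $\alpha$ governs every gap between time points; per-gap
$\alpha_i$ would localize the coupling but multiplies the tuning grid and
is deliberately out of scope, as is learning $\alpha$ by continuous
optimization. Fusion is chain-structured only (no graph or weighted
fusion), groups are whole coefficient rows (no overlap), and there is no
sample weighting. The ADMM path under the logistic loss inherits the
usual caveat that an inexact inner solve makes its convergence slower and
less regular than the accelerated solver's; the package follows the
accelerated method as the default for exactly that reason.
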