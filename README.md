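# tmtl — temporal multi-task learning for progression studies

`tmtl` jointly fits per-time-point prediction models for longitudinal
data: cognitive scores across clinic visits, symptom severity across
months of telemonitoring, case counts across weeks. Each of the `t`
ordered time points is a supervised task over a shared set of `p`
features, with its own (typically shrinking) sample count. Fitting the
tasks jointly — rather than one model per visit — borrows strength across
time and yields coefficient trajectories a clinician can read.

## The model

With `W ∈ R^{p×t}` holding one coefficient column per time point, the
package solves the convex program

    min_W  L(W) + λ₁‖WR‖₁ + λ₂‖WR‖₁,₂ + λ₃‖(WRH)ᵀ‖₁

where

- `R = R(α)` is an upper-triangular, invertible **global temporal
  structure matrix**: column `i` of `WR` is the convex combination
  `ω̄_i = α ω̄_{i−1} + (1−α) w_i` of the current task and its whole
  history, with weights decaying in temporal distance. `α ∈ [0, 0.5]` is
  tuned by cross-validation, so the degree of temporal coupling adapts to
  the data (`α = 0` decouples the tasks entirely).
- `λ₁‖WR‖₁ + λ₂‖WR‖₁,₂` is a **temporal sparse group Lasso**: sparsity
  within tasks plus whole-feature selection across all time points.
- `λ₃‖(WRH)ᵀ‖₁` is a **fused Lasso** on consecutive differences of the
  temporal tasks (`H` the difference operator), enforcing smooth
  progression of effects.
- `L(W)` is `½ Σᵢ‖X_i w_i − y_i‖²` for regression or the per-task
  averaged logistic loss for `{−1, +1}` labels.

Two solvers are provided and agree on the shared optimum: an accelerated
proximal gradient method (default) that exploits an exact decomposition
of the composite proximal operator via the reparameterization `Q = WR`,
and an inexact ADMM with cached per-task Cholesky factorizations. See the
vignette `vignettes/temporal-multitask-learning.Rmd` for the mechanics,
conventions and design decisions.

## Worked example

```r
library(tmtl)
library(dplyr)

# a synthetic 4-visit cohort: 20 features, 4 of them truly predictive,
# effects drifting smoothly over visits, attrition from 80 to 50 samples
spec <- progression_spec(p = 20, n = c(80, 70, 60, 50), s_shared = 4,
                         smooth_step = 0.1, noise_sd = 0.5, seed = 42)
sim <- simulate_progression(spec)

fit <- tmtl_fit(sim$data, target = y, lambda1 = 0.1, lambda2 = 0.1,
                lambda3 = 0.1, alpha = 0.3)
fit
#> <tmtl_fit> regression, solver agm
#>   20 features x 4 tasks; lambda = (0.1, 0.1, 0.1), alpha = 0.3
#>   objective 27.9454 after 31 iterations (converged)

tidy(fit) |>
  group_by(feature) |>
  summarise(row_norm = sqrt(sum(estimate^2))) |>
  arrange(desc(row_norm)) |>
  head(6)
#> # A tibble: 6 × 2
#>   feature row_norm
#>   <chr>      <dbl>
#> 1 x5         1.79
#> 2 x10        1.36
#> 3 x1         0.965
#> 4 x7         0.281
#> 5 x18        0.200
#> 6 x12        0.188

pred <- predict(fit, sim$mtd)
nmse(sim$mtd$y, split(pred$.pred, pred$task))
#> [1] 0.1135575

which(sim$support)
#> [1]  1  5 10 17
```

The three largest coefficient rows (`x5`, `x10`, `x1`) are three of the
four truly active features; `x17`'s true effect is small this draw and
sits below the penalty's noise floor. The normalized MSE of 0.11 means
the fit explains all but ~11% of the variance-scaled error (the
per-task-mean predictor scores exactly 1 by construction).
`tmtl_cv()` tunes `(λ₁, λ₂, λ₃, α)` by k-fold cross-validation;
`autoplot(fit, "coefficients")` draws the fitted trajectories. A
command-line interface over the same functions (simulate / fit / cv /
eval) is installed at `inst/scripts/tmtl`.

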