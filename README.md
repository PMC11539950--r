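# validiv

Instrumental-variable (IV) estimation with a **prediction-based validity
check**. For researchers who want to estimate a causal effect with an
instrument — in epidemiology, Mendelian randomization, economics, policy
evaluation — but who do not want to take the exclusion restriction entirely
on faith, and who may need nonlinear (general additive) model forms in either
stage.

## The idea

Classical two-stage least squares assumes the instrument `z` affects the
outcome `y` only through the treatment `t`, and phrases both IV assumptions
through linear correlation. `validiv` replaces correlation with prediction
under squared loss:

* **Relevance**: `(x, z)` must predict `t` at least `ε` better than `x`
  alone — `loss(t, f(x, z)) ≤ loss(t, f(x)) − ε`.
* **Empirical validity check** (the operational exclusion restriction): the
  second-stage remainder `r = y − ŷ` must *not* be predictable from
  `(x, z)` better than by the model that is identically zero —
  `loss(r, r̂) ≥ loss(r, 0) − ε′`, with `ε′ = γ‖r̃‖²` calibrated from the
  traditional two-stage remainder `r̃` (default `γ = 1%` at `n = 1000`).

The validity check is built into estimation as a constraint. Stage two solves

```
min_β ‖y − X_y β‖²   s.t.   (y − X_y β)ᵀ H_r (y − X_y β) ≤ ε′
```

where `H_r` projects onto the remainder model's feature space — a convex
quadratically constrained quadratic program solved exactly (secular-equation
root finding on the KKT multiplier). The constraint status is the verdict:

| status | meaning |
|---|---|
| `inactive` | check holds at the unconstrained optimum — instrument looks valid |
| `active` | the fit was repaired so the instrument appears valid (only possible with a stage two nonlinear in `t̂`) |
| `infeasible` | **no** coefficients satisfy the check — the proposed instrument is flagged invalid |

A one-stage variant (`fit_one_stage()`) optimizes both stages jointly over a
Rashomon set of near-optimal first stages, which can restore feasibility when
a fixed first stage cannot. Model classes are general additive models:
design-matrix columns like `x1`, `z1^2`, `exp(z1)`, `x1*t_hat`, declared with
`iv_spec()`.

## A worked example

```r
library(validiv)

d   <- sim_iv_data(1000, "valid", seed = 7)           # t = x + z + z² + e₁; y = x + t + e₂
fit <- fit_two_stage(d, preset_spec("quadratic"), gamma = 0.01)
fit
#> <iv_two_stage> validity-constrained two-stage fit (n = 1000)
#>   stage one omega: x1=0.9806, z1=1.0282, z1^2=0.9879
#>   relevance passed: TRUE
#> <iv_stage2> constrained second stage — inactive
#>   beta: x1=0.9974, t_hat=1.0059
#>   objective 3596.6549, constraint 0.216259 <= eps' 35.9665
#>   validity: true percentage 99.99%, passed TRUE
```

The stage-one coefficients recover the generating values `(1, 1, 1)`; the
treatment effect estimate `t_hat = 1.0059` is near the true causal effect 1;
the constraint is slack (`0.22 ≪ 36`) and the remainder is 99.99% as hard to
predict as pure noise, so the instrument passes.

The same pipeline on a design where `z` secretly reaches `y` through a `z³`
mediator:

```r
dn <- sim_iv_data(1000, "non_instrument", seed = 7, phi = 1)
fit_two_stage(dn, preset_spec("quadratic"), gamma = 0.01)
#> ...
#> <iv_stage2> constrained second stage — infeasible
#>   no feasible solution: min constraint 4488.2 > eps' 141.921
#>   validity: true percentage 68.38%, passed FALSE
```

Even the best possible stage-two coefficients leave a remainder the
instrument can predict far too well: the variable is flagged as not an
instrument.

Fitted objects support `tidy()`, `glance()` and (for study results)
`autoplot()`. Monte-Carlo drivers reproduce the package's studies:
`run_confusion()` (detection rates over 2000 replicates),
`run_misspecification()` (detecting and fixing an insufficient first stage),
`run_robustness()` (stability of the effect estimate across instrument
strengths), `run_theorem_suite()` (the feasibility taxonomy across model
classes). A thin command-line front end lives in `inst/cli/validiv.R`
(subcommands `simulate`, `fit2`, `fit1`, `check`, `experiment`).

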