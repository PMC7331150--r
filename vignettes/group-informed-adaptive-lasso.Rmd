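---
title: "Group-informed adaptive lasso for high-dimensional Cox models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-informed adaptive lasso for high-dimensional Cox models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In oncology cohorts with genomic profiling, the outcome of interest is
typically a censored time to event, the candidate predictors number in the
hundreds or thousands of biomarkers, and those biomarkers come organised in
prespecified, disjoint functional groups — biological pathways, or data
modalities. The standard lasso for the Cox model selects prognostic
biomarkers in this `p >> n` regime, but it is notoriously liberal: many of
the features it selects are false positives, and it is blind to the group
structure. `coxadapt` implements an adaptive-lasso approach in which the
per-biomarker penalty weights carry group-level evidence, so a biomarker is
penalized less when it *and* the pathway it belongs to look prognostic, and
more when both look like noise.

## Model

With `n` patients, `p` standardized biomarkers `X`, and right-censored
outcomes, the Cox partial log-likelihood `l(beta, X)` (Breslow convention
for ties) is penalized as

    l(beta, X) - lambda * sum_j W_j |beta_j|

Unit weights `W_j = 1` give the standard lasso. `coxadapt` constructs `W`
from the training data in eight ways. Write `SW_k` for the squared Wald
statistic `(beta_hat_k / se_k)^2` of the univariable Cox fit of biomarker
`k`, and for a group `r` let `ASW_r` and `MSW_r` be the mean and maximum of
its members' `SW` values. The schemes are:

| scheme | weight for biomarker `k` in group `r` | granularity |
|---|---|---|
| `AC` | reciprocal of the group mean of absolute univariable coefficients | group |
| `PCA` | `1 / |beta_hat|` of the group's first principal-component score | group |
| `lasso_pca` | two-step: lasso pre-selection, then PC1 of the selected members per group; unselected groups inherit the maximum selected-group weight | group |
| `SW` | `1 / SW_k` | biomarker |
| `ASW` | `1 / ASW_r` | group |
| `MSW` | `1 / MSW_r` | group |
| `ASWxSW` | `1 / (ASW_r * SW_k)` | both |
| `MSWxSW` | `1 / (MSW_r * SW_k)` | both |

The product schemes are the interesting ones: `MSWxSW` penalizes a
biomarker lightly only when its own evidence *and* the best evidence in its
group are strong, which is what cuts the false discovery rate without
starving the model of true signals. Since `MSW_r >= ASW_r`, the `MSWxSW`
weight never exceeds the `ASWxSW` weight: active groups with any prognostic
member are treated gently.

The shrinkage parameter is chosen by maximizing the cross-validated partial
log-likelihood (Verweij–van Houwelingen): for each fold `k`,
`cvl_k(lambda) = l(beta_{-k}(lambda)) - l_{-k}(beta_{-k}(lambda))`, summed
over folds; folds are event-stratified and seed-deterministic. Five folds
are the default.

## A worked fit

```{r, message = FALSE}
library(coxadapt)

cfg <- scenario_config(3, p = 100, group_sizes = rep(25, 4),
                       n_train = 150, n_valid = 150, q = 4, l = 1)
sim <- simulate_dataset(cfg, seed = 1)
uni <- univariable_cox(sim$train)
w <- adaptive_weights(sim$train, "MSWxSW", uni = uni)
fit <- cox_adaptive_lasso(sim$train, weights = w, seed = 1)
fit
dplyr::filter(tidy(fit), selected)
ipcw_auc(predict(fit, sim$valid), sim$valid$time, sim$valid$status,
         horizon = 5)
```

The univariable table is a pure function of the training data and can be
shared across schemes; `run_benchmark()` does exactly that.

## What the simulator emulates

The generator reproduces a breast-cancer-like trial design: biomarkers are
standard Gaussian with a block-autoregressive correlation — consecutive
blocks of 5 features with `cor(x_i, x_j) = 0.8^|i-j|` inside a block and
independence across blocks; event times are exponential with baseline
median survival 8 years and proportional hazards `exp(X beta)`; censoring
is uniform on (2, 6) years, independent of the event process, reflecting a
trial with two-year follow-up and four-year accrual. Under the null this
censors about 71% of subjects (closed form `(2/log 2)(2^{-1/4} -
2^{-3/4})`), and all bundled scenarios stay inside the 55–78% band.

Eight scenario presets (`scenario_config(1)` … `scenario_config(8)`) vary
the number of active groups `l`, active biomarkers `q` (split equally over
the active groups) and the hazard-ratio range, from a complete null to
dense-weak and sparse-strong configurations, in two group-size layouts
(20×50, or 10×25 + 10×75). Active effects are protective, drawn uniformly
on the log-hazard-ratio interval per replicate.

Design choices where the design was genuinely open:

* **Active positions.** Active biomarkers occupy the leading positions of
  each active group, which places them inside common correlation blocks.
  This is configurable (`active_positions`); a sensitivity check showed
  that spreading actives across blocks makes weak-effect scenarios much
  harder (dense-weak FDR rises from ~0.27 to ~0.7), because clustered weak
  effects reinforce each other's marginal association.
* **Effect redraws.** `beta` is redrawn each replicate; `fixed_beta` allows
  holding one draw fixed across replicates.
* **Wald form.** The squared Wald statistic is the default (`wald =
  "chisq"`); `"abs_z"` is exposed. The squared form matches the reference
  sparse-strong benchmark tables markedly better than `|z|` in our runs.
* **PC scores.** Principal-component scores are rescaled to unit
  (population) variance before their univariable Cox fit, so the PC
  coefficient lives on the scale of a standardized biomarker. A singleton
  group's PC1 is the (centred) member itself.
* **Standardization.** The population-SD convention (divisor `n`) is used
  throughout, matching the simulator's exact unit-variance contract. For
  split validation the default re-standardizes within each training split
  and applies the training centring/scale to the held-out part.

What the simulator does *not* emulate: non-proportional hazards,
non-Gaussian or heavy-tailed expression distributions, dependent censoring,
overlapping pathways, and batch structure. Benchmarks passing under this
generator show correct mechanics and the claimed ordering of methods under
the stated law, not performance guarantees on any particular real dataset.

## Evaluation machinery

Selection is scored against the known active set at two levels.
`selection_metrics()` computes `FDR = FP/(TP+FP)`, `FNR = FN/(TP+FN)` and
`F1 = 2TP/(2TP+FP+FN)`; a rate with an empty denominator is defined as 0 by
default, so under a complete null the mean FDR across replicates equals the
proportion of replicates selecting anything (an `"na"` mode exists for
sensitivity). `group_metrics()` lifts both sets to groups by the any-member
rule before applying the same formulas.

Discrimination is the cumulative-cases / dynamic-controls AUC at a horizon
(default 5 years) with inverse-probability-of-censoring weights from the
Kaplan–Meier estimate of the censoring distribution of the evaluation data
itself: cases observed by the horizon weigh `1/G(T_i^-)`, controls at risk
past it weigh `1/G(t)`, ties in the marker count one half. Weights with a
zero denominator drop their terms with a warning — relevant here because
the censoring support ends at 6 years, so horizons near 6 can make `G`
small.

## Numerical choices

* The weighted fit is solved through the exact rescaling identity (columns
  divided by `W`, coefficients divided back), with infinite-weight columns
  removed before fitting so their coefficients are exact zeros; a single
  remaining column is solved by direct 1-D maximization.
* Coordinate descent (glmnet) runs with convergence threshold `1e-6` —
  measured to leave the selection path identical over the region where the
  cvl optimum lives while being substantially faster than tighter settings
  — and every *returned* solution is then polished by an active-set Newton
  step until the Karush–Kuhn–Tucker stationarity conditions hold to `1e-5`
  on the gradient scale (typically `1e-9` after polish). `kkt_check()`
  certifies any fit.
* The penalty path has 100 log-equispaced values from the KKT bound
  `lam_max = max_j |dl/dbeta_j(0)| / W_j` down to `lam_max/100`, the usual
  `p > n` convention.
* Univariable fits for all `p` biomarkers run as one vectorized
  Newton–Raphson (damped steps, `|beta| <= 15` cap flagged for monotone
  likelihoods), which is what makes thousands of replicate-level weight
  constructions affordable.

## Benchmark scales

The bundled acceptance script runs 50 replicates per scenario, the
acceptance tests in the suite 10 (6 for the nine-method directional
comparison); both use the full reference problem size `n = 500`, `p =
1000`, 20 groups. At these scales the pipeline reproduces the reference
sparse-strong results closely (standard lasso FDR 0.81, `MSWxSW` about 8.4
selected with FDR 0.06, validation AUC 0.88/0.89) and the direction of
every adaptive scheme's FDR improvement over the standard lasso in all
alternative-scenario comparisons we run.

## Known limitations

* In the dense-weak scenario (all 20 groups active with 100 tiny effects)
  the pipeline selects fewer biomarkers (means in the 60s–70s) than the
  reference value of 95.8 and lands at a higher FDR (about 0.27 vs 0.18). The cvl
  optimum is interior, so this is not a path artifact; the remaining
  degrees of freedom (exact active indices, per-replicate vs fixed effect
  draws) are not recoverable from the benchmark description. Replicate
  variance of the selected-set size is very large in this scenario.
* Overlapping groups are out of scope (duplication of biomarkers across
  groups would be the extension); so are Efron tie handling, elastic-net
  mixing, stratified baselines and left truncation.
* Exact numeric parity with any particular historical glmnet configuration
  is not promised — path grids and standardization settings differ across
  versions — only statistical parity at the replicate level.
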