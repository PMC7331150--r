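# coxadapt

Group-informed adaptive lasso variable selection for high-dimensional Cox
proportional-hazards models.

## What problem this solves, and for whom

Biostatisticians analysing censored survival outcomes against hundreds or
thousands of biomarkers usually know more than the data matrix: the
biomarkers come in prespecified disjoint groups — biological pathways, or
distinct data modalities. The standard Cox lasso ignores that structure and
selects far too many false positives. `coxadapt` builds **adaptive-lasso
penalty weights that combine pathway-level and biomarker-level evidence**,
so that a biomarker is penalized lightly only when it, and the group it
belongs to, both look prognostic.

The estimator maximizes the penalized partial log-likelihood

```
l(beta, X) - lambda * sum_j W_j |beta_j|
```

with eight weighting schemes for `W`. Writing `SW_k = (beta_hat_k/se_k)^2`
for the univariable Cox Wald statistic of biomarker `k`, and `ASW_r` /
`MSW_r` for the mean / maximum of `SW` over group `r`:

* `AC` — reciprocal group mean of `|beta_hat|`;
* `PCA` — reciprocal effect of the group's first principal component;
* `lasso_pca` — lasso pre-selection, then PC1 of the selected members;
* `SW`, `ASW`, `MSW` — reciprocals of `SW_k`, `ASW_r`, `MSW_r`;
* `ASWxSW`, `MSWxSW` — reciprocals of the products `ASW_r * SW_k`,
  `MSW_r * SW_k`, the bi-level schemes that cut the false discovery rate
  hardest without starving the model of true signals.

`lambda` is chosen by maximizing the cross-validated partial log-likelihood
(Verweij–van Houwelingen, event-stratified 5-fold CV). The package also
ships the full simulation benchmark around the method: a survival-data
generator with block-autoregressive correlated biomarkers, selection
metrics (FDR / FNR / F1 at biomarker and group level), the IPCW
time-dependent AUC, a replicated benchmark runner and a split-validation
pipeline for real datasets.

## Worked example

Simulate a 150-patient training/validation pair with 100 biomarkers in 4
pathways, 4 true (protective) effects in pathway 1, fit the `MSWxSW`
adaptive lasso, and evaluate it:

```r
library(coxadapt)

cfg <- scenario_config(3, p = 100, group_sizes = rep(25, 4),
                       n_train = 150, n_valid = 150, q = 4, l = 1)
sim <- simulate_dataset(cfg, seed = 1)
sim$train
#> <survival_dataset> 150 patients, 100 biomarkers in 4 groups
#>   events: 41 (72.7% censored); follow-up 0.0599-5.99
#>   group sizes: grp01=25, grp02=25, grp03=25, grp04=25

w <- adaptive_weights(sim$train, "MSWxSW")
fit <- cox_adaptive_lasso(sim$train, weights = w, seed = 1)
fit
#> <cox_alasso> MSWxSW weighting: 5 of 100 biomarkers selected
#>   lambda = 3360 (path position 78/100), cvl = -205.253, 5-fold CV

dplyr::filter(tidy(fit), selected)
#> # A tibble: 5 × 5
#>   feature_id group   weight estimate selected
#>   <chr>      <fct>    <dbl>    <dbl> <lgl>
#> 1 bm0001     grp01 0.000817 -0.0528  TRUE
#> 2 bm0002     grp01 0.000535 -0.277   TRUE
#> 3 bm0003     grp01 0.000343 -0.955   TRUE
#> 4 bm0004     grp01 0.000616 -0.00567 TRUE
#> 5 bm0005     grp01 0.000821 -0.162   TRUE

sim$active
#> [1] "bm0001" "bm0002" "bm0003" "bm0004"

ipcw_auc(predict(fit, sim$valid), sim$valid$time, sim$valid$status,
         horizon = 5)
#> # A tibble: 1 × 5
#>   horizon   auc n_cases n_controls undefined
#>     <dbl> <dbl>   <int>      <int> <lgl>
#> 1       5 0.847      49         19 FALSE
```

The fit recovers all 4 active biomarkers (plus one correlated neighbour,
`bm0005`) out of 100, all from the correct pathway; its penalty weights are
orders of magnitude smaller for pathway-1 members than for the noise
pathways; and the selected model discriminates 5-year outcomes in the
independent validation set with AUC 0.85. `tidy()`, `glance()`,
`autoplot()` and `predict()` work on every fit; `run_benchmark()` /
`aggregate_benchmark()` replicate this whole loop over scenarios and
methods, and `split_validate()` runs the repeated 60/40 train/validation
protocol on your own data (`read_survival_dataset()` loads the three CSVs:
biomarker matrix, survival table, group map).

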