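# picuree

Prediction of resting energy expenditure (REE) in critically ill children.

Accurate REE assessment drives nutritional prescription in the pediatric
intensive care unit (PICU). Indirect calorimetry — measuring oxygen
consumption (VO₂) and carbon dioxide production (VCO₂) and converting them
with the modified Weir equation,

    REE [kcal/day] = 1440 · (3.941·VO₂ + 1.106·VCO₂),   VO₂, VCO₂ in L/min

— is the gold standard but rarely available; classical predictive equations
(Harris–Benedict, Schofield, Oxford, FAO/WHO/UNU, Talbot tables, the
VCO₂-based Mehta equation) are often badly biased in critical illness.
`picuree` implements, end to end:

* **Calorimetry processing** — steady-state detection (≥5-minute windows
  with <5% RQ and <10% gas/ventilation variation), RQ plausibility filtering
  (RQ outside [0.67, 1.3] excluded), Weir conversion.
* **Anthropometry** — LMS growth z-scores (`z = ((x/M)^L − 1)/(L·S)`) with
  WHO-style stunting/wasting/overweight/obesity classification and the
  age-availability limits of the reference charts.
* **Equation registry** — the ten classical estimators from a versioned,
  cited coefficient/lookup CSV registry.
* **Input selection** — an elitist genetic algorithm jointly evolving a
  feature mask and a distribution-matched train/test split, scored by blind
  cross-predictive performance (a contract-level reimplementation of the
  published "TWIST" system).
* **Regression** — a 4-hidden-unit perceptron with a train/test *reversal*
  protocol giving one blind prediction per record.
* **Evaluation** — MAE, mean relative error, the two accuracy percentages
  `100·(1 − MAE/mean)` and `100·(1 − MRE)`, R², and the two-sample F test
  `(sd_true/sd_pred)²`.
* **Synthetic cohorts** — a calibrated generator (n = 257-style PICU cohort
  with known ground truth) so everything is testable without patient data.

## Worked example

```r
library(picuree)

# 1. a synthetic PICU cohort with known ground truth
cohort <- generate_cohort(cohort_spec(seed = 42))
round(c(n = nrow(cohort), median_age = median(cohort$age),
        mean_vo2 = mean(cohort$vo2), mean_rq = mean(cohort$rq),
        mean_ree = mean(cohort$measured_ree)), 3)
#>          n median_age   mean_vo2    mean_rq   mean_ree
#>    257.000      2.018      0.088      0.773    607.640

# 2. calorimetry: steady-state window + Weir REE for one breath series
series <- generate_breath_series(cohort[1, ], cohort_spec(seed = 42))
gas <- summarize_measurement(series)
round(c(start = gas$window$start, end = gas$window$end,
        rq = gas$rq, ree = gas$ree), 2)
#>  start    end     rq    ree
#>   8.00  22.00   0.69 358.43

# 3. classical predictive equations (kcal/day; Mehta NA: not ventilated)
round(evaluate_all(load_equation_registry(), as.list(cohort[1, ])), 0)
#> harris_benedict ... schofield_w 503 ... talbot_weight 495 ... mehta NA

# 4. GA input selection + blind neural prediction + comparison statistics
cfg <- experiment_config("ds1", "all",
                         ga = ga_config(population_size = 20, generations = 15),
                         mlp = mlp_spec(), seed = 42)
report <- run_experiment(cfg, cohort)
report$selection$selected_features
#> [1] "male" "female" "mechanically_ventilated" "z_hfa" "vo2" "rq"
round(with(report$ann_metrics$pooled,
           c(mae = mae, accuracy = accuracy_abs, r2 = r2, f = f_statistic)), 3)
#>      mae accuracy       r2        f
#>    2.428   99.600    1.000    1.003
round(sapply(report$equation_metrics[c("talbot_weight", "harris_benedict",
                                       "mehta")],
             function(x) x$accuracy_abs), 1)
#> talbot_weight harris_benedict         mehta
#>          82.1            61.0          88.7
```

Reading the output: the generator's marginal moments match its calibration
targets (mean VO₂ ≈ 0.09 L/min, mean RQ ≈ 0.77); the steady-state detector
recovers the planted window (minutes 8–22) and the Weir REE of the window
means; under the `weir_exact` ground-truth mechanism the GA keeps gas
variables and the blind network is near-exact (accuracy 99.6%, R² = 1.00),
while the classical equations land in the 60–89% accuracy range with the
Harris–Benedict equation worst and the VCO₂-based equation best — the same
ordering reported for real PICU cohorts.

There is also a CLI (`inst/cli/picuree`):
`simulate`, `equations`, `analyze`, `evaluate`; exit codes 0 / 2 (config) /
3 (data). Column semantics are documented in
`inst/extdata/data_dictionary.csv`.

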