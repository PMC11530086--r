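# iohdef

Data-driven selection of intraoperative hypotension (IOH) definitions by
their association with postoperative outcomes.

## The problem

Low mean arterial pressure (MAP) during anesthesia is linked to
postoperative harm, but studies operationalize "hypotension" in over a
hundred different ways — lowest MAP sustained for some minutes, cumulative
minutes under a threshold, absolute or relative time below 50–80 mmHg —
and the choice changes both incidence and estimated effects. `iohdef`
implements a two-stage, split-sample procedure for choosing among candidate
definitions by predictive association with an outcome:

1. **Shaping stage** (half the cohort): for each candidate definition
   `d` and outcome `y`, fit
   `g(E[y]) = f(IOH_d) + covariates` — logistic for 30-day mortality,
   linear for log-transformed, 1%-trimmed hospital and PACU length of stay
   — where `f` is a 3-df natural cubic spline of the winsorized definition
   value (plus a spike-at-zero indicator for time-below definitions) and
   the covariates are sex, age, BMI, duration of surgery, time from
   admission to surgery, surgical specialty, ASA class and comorbidity
   score. Each model is scored by 10-fold cross-validation with 40
   repetitions (Brier score for mortality, MSE for length of stay); the
   smallest score wins, and a 0.95 Akaike-weight confidence set
   (`w_i ∝ exp(−ΔAIC_i/2)`, accumulated in decreasing order past 0.95)
   quantifies selection uncertainty.
2. **Estimation stage** (the other half): refit the winning definition's
   model, report adjusted effect curves for a reference patient, odds/LOS
   ratios at clinically relevant exposures (MAP 50/65/75 mmHg; 5/10 min;
   5/10% of anesthesia time), and each variable group's contribution to
   cross-validated performance.

Upstream of the models, the package cleans raw intraoperative
blood-pressure series with six artifact rules (absolute systolic/diastolic
cut-offs, pulse-pressure consistency, a per-patient 3-SD filter) and
interpolates to a homogeneous 15-second MAP grid. A synthetic perioperative
cohort generator with known ground truth (recording dialects, injected
artifacts, controllable hypotensive episodes, outcomes driven through a
chosen "true" definition) makes the whole pipeline testable end to end.

## Worked example

Simulate a 4,000-patient cohort whose mortality risk is driven through
*relative time with MAP < 80 mmHg* (1 log-odds per SD), run the full
two-stage analysis, and see whether the pipeline finds the planted
definition:

```r
library(iohdef)

cfg <- run_config(
  n_patients = 4000, seed = 42, reps = 5, k = 10,
  truth = truth_config(4000, seed = 42, target_mortality = 0.05,
                       beta_mortality = 1, baseline_map_mean = 90,
                       true_definition = "rel_t_lt80"))
run <- run_all(cfg, quiet = TRUE)
print(run)
#> End-to-end IOH definition-selection run
#>   mortality best = rel_t_lt80   (score 0.0513460, confidence set 1)
#>   hlos      best = abs_t_lt80   (score 0.6536453, confidence set 2)
#>   pacu      best = rel_t_lt80   (score 0.1524272, confidence set 2)

head(run$selection$mortality$table, 5)
#>   definition   score rank    weight in_confidence_set
#> 1 rel_t_lt80 0.05135    1 1.000e+00              TRUE
#> 2 abs_t_lt80 0.05349    2 9.308e-10             FALSE
#> 3 rel_t_lt75 0.05537    3 1.089e-13             FALSE
#> 4 abs_t_lt75 0.05637    4 1.176e-18             FALSE
#> 5 sust_15min 0.05804    5 3.540e-21             FALSE
```

The planted definition wins the cross-validated Brier ranking (score
0.0513, next candidate 0.0535) and is the sole member of the 0.95
confidence set. The estimation half then quantifies its association for
the reference patient (male, 53 y, BMI 26, 1.7 h surgery, ASA 2):

```r
run$estimation$mortality$effects
#>   point ref_exposure contrast     lo    hi      scale
#> 1  0.05            0    1.090 0.3964 2.997 odds ratio
#> 2  0.10            0    1.389 0.5405 3.571 odds ratio

head(run$estimation$mortality$contribution, 4)
#>   variable cv_full cv_without    delta
#> 1      ioh  0.0439     0.0522 0.008349
#> 3      age  0.0439     0.0505 0.006672
#> 8      asa  0.0439     0.0447 0.000863
#> 2      sex  0.0439     0.0442 0.000337
```

Spending 10% of the anesthetic below 80 mmHg carries an estimated odds
ratio of 1.39 (95% CI 0.54–3.57) versus never dipping below 80; removing
the IOH block from the model costs more cross-validated Brier score
(+0.0083) than removing any adjustment covariate, i.e. the exposure is the
model's most informative block, as planted. Note the two stages: the
shaping half *selects* with near-certainty, while the independent
estimation half gives an honest — and at this n, wide — interval for the
effect size.

Individual stages are available as plain functions: `clean_artifacts()`,
`interpolate_to_grid()`, `compute_all_definitions()`, `ioh_registry()`,
`build_model_matrix()`, `cross_validate()`, `shape_outcome()`,
`fit_best()`, `effect_curve()`, `variable_contribution()`,
`sensitivity_analysis()`. A thin command-line wrapper lives at
`inst/cli/iohdef.R`. The methods vignette
(`vignettes/ioh-definition-selection.Rmd`) documents the model, its
assumptions, all tunable parameters and the generator's scope.

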