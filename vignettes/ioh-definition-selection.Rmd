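---
title: "Selecting a definition of intraoperative hypotension by its association with outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting a definition of intraoperative hypotension by its association with outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iohdef)
```

## The problem

Intraoperative hypotension (IOH) — low mean arterial pressure (MAP) during
anesthesia — is associated with postoperative harm, but the literature uses
well over a hundred different operational definitions of "hypotension", and
the choice of definition changes both the apparent incidence and the
estimated effect. `iohdef` implements a data-driven procedure for choosing
among candidate IOH definitions by how well each one predicts an outcome of
interest: 30-day mortality, hospital length of stay (hLOS), or
post-anesthesia care unit length of stay (PACU-LOS).

The procedure is a two-stage split-sample design:

1. **Shaping stage.** The cohort is split at random into two equal halves.
   On the first half, one regression model per candidate definition is fit
   (logistic for mortality, linear for log length of stay) and scored by
   repeated cross-validation — the Brier score for the binary outcome, the
   mean squared error (MSE) on the log scale for the metric ones. The
   definition with the smallest cross-validated score is selected, and an
   Akaike-weight confidence set quantifies how sure that selection is.
2. **Estimation stage.** On the second, untouched half, the winning
   definition's model is refit and interpreted: adjusted risk/LOS curves
   for a reference patient, effect sizes at clinically relevant exposure
   values, and the contribution of each variable to predictive performance.

Because the two halves are independent, the estimation stage is not
contaminated by the multiple comparisons of the shaping stage.

## The candidate definitions

All definitions are computed from a cleaned, homogeneous 15-second MAP
sequence per anesthetic (`map_grid`). Four families are supported
(`ioh_registry()`):

* `sust_Nmin` — *lowest MAP sustained for N minutes*: the smallest
  threshold T such that MAP stayed at or below T continuously for N
  minutes. Computed as the minimum over all windows of `4N` consecutive
  ticks of the within-window maximum (a sliding-window max-then-min).
* `cum_Nmin` — *lowest MAP for N cumulative minutes*: the smallest T such
  that the total, possibly interrupted, time at or below T reaches N
  minutes; this is the `4N`-th order statistic of the grid.
* `abs_t_ltX` — *absolute time with MAP under X mmHg* (minutes; strict
  comparison, each tick counting 0.25 min).
* `rel_t_ltX` — that time divided by the duration of anesthesia.

Durations are 1, 3, 5, 10 and 15 minutes and thresholds 50–80 mmHg in
steps of 5, giving 24 definitions (`tables_24`); a 22-entry variant without
the 15-minute durations (`methods_22`) is also provided, since both counts
circulate in the comparison literature. Useful identities double as test
oracles: `cum ≤ sust` at equal duration (relaxing contiguity can only lower
the threshold), both families are non-decreasing in duration, and the
time-below families are non-decreasing in the threshold.

**Tick-exposure convention.** One grid tick represents 15 s = 0.25 min of
exposure, so "N minutes" is exactly `4N` ticks and a grid of `n` ticks
carries `n/4` minutes of anesthesia time. This makes
`abs_t_ltX ≤ duration` and `rel_t_ltX ∈ [0, 1]` exact identities even when
every tick is below threshold. The span from first to last measurement
(one tick less) is kept separately as `span_min`.

## Signal cleaning

Anesthesia records contain artifacts (flushes, transducer errors, cuff
failures). Six rules are applied per patient (`clean_artifacts()`):

1. systolic ≥ 300 mmHg; 2. systolic ≤ 20 mmHg; 3. diastolic ≤ 5 mmHg;
4. diastolic ≥ 225 mmHg; 5. systolic ≤ diastolic + 5 mmHg;
6. any channel outside mean ± 3 SD for that patient.

Rules 1–5 are absolute per-sample cut-offs on the raw values; a sample
violating several rules is attributed to the lowest-numbered one. Rule 6's
mean and SD are computed once on the survivors of rules 1–5 and not
iterated — iterating the 3-SD filter is a different (non-idempotent)
filter, and nothing in its usual formulation calls for it. Whether the 3-SD
rule watches MAP only or all three channels is ambiguous in the field's
descriptions; the package applies it to all channels by default with a
`rule6_channels = "map"` option, asserting neither as canonical. Samples
with a missing MAP channel are completed as `(sbp + 2·dbp)/3` when both
pressures are present, otherwise dropped with a reason code. Cleaned series
are then interpolated linearly to the 15-s grid between the first and last
retained measurement (never extrapolated); patients with no valid pressure
or fewer than two surviving samples are excluded with logged reasons.

## The model battery

Each candidate model contains one definition's exposure block plus fixed
adjustment covariates (`build_model_matrix()`):

* IOH definition: winsorized at the 99th percentile, natural cubic spline
  with 3 df (4 df in a sensitivity variant). For the time-below families an
  extra binary column flags exposure exactly zero — these distributions
  have a large point mass at zero (many patients are never hypotensive by a
  given threshold), and the spike would otherwise distort the spline.
* Sex, surgical specialty and ASA class as dummies (references: male,
  "Urology, gynecology, general surgery", ASA 2 — the cohort's "average
  patient").
* Age and BMI (winsorized) as 2-df natural splines; duration of surgery
  (winsorized), time from admission to surgery, and comorbidity score as
  3-df natural splines.

Interior knots sit at equally spaced quantiles, boundary knots at the data
extremes; all caps and knots are recorded so the estimation stage can
rebuild the design with the same *rules* on its own half. Knots that
collide on heavily tied data (the spike-at-zero metrics, comorbidity
scores) are dropped, shrinking that block's dimension; with too few
distinct values the block degrades to a linear term with a warning.

Winsorization caps use the order-statistic (type-1) quantile: the cap is
then an attained value, which makes winsorization exactly idempotent.
Spline knots use the conventional linear-interpolation (type-7) quantile.

hLOS and PACU-LOS are modeled as natural logs. Patients who die before
discharge have their hospital stay set to +∞, and the top
`ceil(0.01·n)` stays are trimmed (deaths first, ties broken by patient id
for determinism), so the model describes the 99% "best" patients; 1.5% and
2% trims are sensitivity variants. If deaths before discharge ever exceed
the trim budget (only possible in configurations with mortality above
roughly the trim fraction), the surplus infinite rows are excluded with a
warning and logged. PACU-LOS is trimmed the same way; patients admitted
directly to the ICU have no PACU stay and are excluded from that outcome.

Logistic models are fit by the package's iteratively reweighted least
squares (tolerance 1e-8 on coefficients, max 100 iterations); the test
suite verifies agreement with `stats::glm.fit` to ~1e-12. Quasi-separated
fits (any coefficient beyond 15 on standardized columns, or
non-convergence) are flagged and excluded from the ranking — unless every
candidate is flagged (tiny event counts), in which case the ranking is
retained with a message rather than returned empty. Calibration of the
mortality models can be checked with the Hosmer–Lemeshow Ĉ statistic on
deciles of predicted risk (df = groups − 2).

## Cross-validated selection

`cross_validate()` scores each definition's model by k-fold CV repeated R
times (defaults k = 10, R = 40), stratifying folds by outcome for
mortality so every training fold sees events. The reported score is the
mean over all folds and repetitions. Winsorization caps and knots are
computed once on the full half being modeled, before CV — mirroring a
parameterize-then-validate workflow; the mild information leakage this
implies is deliberate and recorded in the output metadata so either
convention can be audited. Fold partitions are derived from one seed and
shared across definitions (and across the variable-contribution refits)
for comparability.

Ranking is by ascending score with ties broken by fewer parameters, then
registry order. The 0.95 confidence set is built from Akaike weights
`w_i ∝ exp(−Δ_i/2)` of single full-half fits: models are accumulated in
decreasing weight order until the cumulative weight first exceeds 0.95,
and the model that crosses the boundary is included. (The weights are a
full-data quantity in the model-confidence-set framework, which is why
they are not computed from CV refits.)

## Estimation stage

`fit_best()` refuses any overlap between the halves ("split leakage").
Effect curves (`effect_curve()`) show the predicted outcome across the
exposure range for a reference patient — male, 53 years, BMI 26, 1.7 h
surgery, one day from admission to surgery, reference specialty, ASA 2,
comorbidity 0 — on the probability scale for mortality and back-transformed
(`exp`) to days/hours for the LOS outcomes. Intervals are delta-method 95%
bands on the linear predictor, transformed. Effect sizes
(`effect_at_points()`) contrast clinically relevant exposures — MAP 50, 65
and 75 mmHg for the level-based families; 5 and 10 minutes, or 5% and 10%
of anesthesia time, for the time-below families — against a reference
exposure, reported as odds ratios (mortality) or LOS ratios. The reference
exposure is a design choice the source methodology leaves open: MAP 75 mmHg
(the highest listed clinically relevant level) for the level families, and
zero time below threshold (the natural null exposure) for the time-below
families; both are configurable.

`variable_contribution()` removes one variable group at a time (the IOH
block with its indicator, sex, age, BMI, duration, time to surgery,
specialty, ASA, comorbidity) and reports the increase in cross-validated
Brier/MSE under shared fold partitions. `sensitivity_analysis()` re-runs
the shaping stage under the trim and spline-df variants and tabulates rank
changes.

## The synthetic cohort generator

The package ships a generator (`truth_config()`, `generate_cohort()`)
whose point is testability: every downstream stage can be exercised against
known ground truth without any data download.

Per patient, MAP is a constant baseline (between-patient normal, mean 86,
SD 7 mmHg) plus stationary AR(1) noise (SD 4 mmHg, lag-1 correlation 0.9
at 15 s), with rectangular hypotensive episodes subtracted — a Poisson
number per hour (default 1.5/h) with uniform depth 10–35 mmHg and duration
1–10 min. Systolic and diastolic channels are reconstructed around MAP via
a patient-specific pulse pressure, so that `map = (sbp + 2·dbp)/3` holds
for clean samples. Records are emitted in two dialects — every 2 minutes or
every 15 seconds, reflecting older and newer monitor export intervals (40%
/ 60% by default) — and artifacts are injected per sample (default rate
0.5%), each constructed to violate one of the six cleaning rules chosen
uniformly, with a hidden truth flag so cleaning sensitivity is measurable.
Covariate marginals loosely match a large mixed surgical cohort (age
median ≈ 53, BMI ≈ 25.7, mostly ASA 1–2, six specialty strata); they are
defaults, not calibration targets.

Outcomes are generated from the models the analysis assumes: the configured
"true" definition is evaluated on the artifact-free 15-s grid, standardized
across the cohort, and enters a logistic model for 30-day death and
log-normal models for hLOS (median 5.1 days) and PACU-LOS (median 2.1 h)
with configurable slopes, alongside modest covariate effects. The mortality
intercept is calibrated by root-finding so the covariate-only model hits a
target marginal prevalence (default 0.9%); with the intercept anchored this
way, raising the exposure slope provably raises prevalence. Seeding is
counter-based per patient, so enlarging a cohort never reshuffles earlier
patients and identical configs are bit-identical.

The generator emulates the *statistical* structure the analysis needs, not
operating-room physiology: there are no drug or vasopressor dynamics, no
circadian or surgical-phase trends, and episode edges are rectangular
rather than ramped. Passing tests therefore demonstrate that the pipeline
recovers what it assumes — correct algorithms, calibrated inference — not
that any particular clinical cohort behaves like the simulator.

## Numerical and scale choices

* Rolling-window maxima use binary composition of window maxima
  (`O(log w)` vectorized passes), verified against naive scans.
* The k-th order statistic uses partial sorting.
* CV refits warm-start from the full-half coefficients; fits agree with
  cold starts to the IRLS tolerance.
* Desk-scale test and demo configurations use elevated baseline mortality
  (2–6%) and/or shorter surgeries than the generator defaults: a
  26-parameter logistic battery needs more events than a 0.9%-prevalence
  cohort of a few thousand patients can supply. These are test-design
  choices, stated in each test; the generator defaults are unchanged.
  The test suite runs the headline experiments at n = 20,000 (parameter
  recovery, 20 cohorts), n = 8,000 (definition recovery, 25 cohorts) and
  n = 500 (null calibration, 100 cohorts); the acceptance script runs a
  full study replica at n = 4,000.
* The null-calibration experiment ranks the univariable battery: at n = 500
  with ~25 events the multivariable models are routinely
  separation-flagged, which would leave ranks undefined.

## Known limitations

* AIC-based weights compare models fit to the same rows; definitions that
  drop patients (records shorter than their window) are only comparable
  when the affected patients coincide, which holds for the default
  generator (minimum surgery length above the longest window) but is the
  user's responsibility on external data.
* The 3-SD rule can clip genuine deep hypotensive episodes in short records
  — a known property of cut-off filters, visible in the generator when
  episodes are deep and rare; the truth-consistency tests therefore use
  moderate episode depths.
* Strict single-pass idempotence of rule 6 is a property of typical data,
  not a theorem: removing an extreme sample shrinks the SD, and in
  adversarial configurations a second pass could remove more.
* Effect-size confidence intervals are delta-method (Wald) intervals on the
  linear predictor; profile-likelihood intervals are not implemented.
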