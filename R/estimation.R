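# Estimation stage: fit the selected definition's model on the independent
# half, produce adjusted effect curves, effect sizes at clinically relevant
# exposure points, variable contributions, and sensitivity analyses.

#' The reference ("average") patient used for adjusted curves
#'
#' Male, 53 years, BMI 26, 1.7 h of surgery, one day from admission to
#' surgery, specialty "Urology, gynecology, general surgery", ASA 2,
#' comorbidity score 0.
#'
#' @param ... Named overrides of individual fields.
#' @return Named list of covariate values.
#' @export
reference_patient <- function(...) {
  ref <- list(sex = "male", age = 53, bmi = 26,
              duration_surgery = 1.7 * 60, time_to_surgery = 1,
              specialty = REF_LEVELS$specialty, asa = 2L,
              comorbidity_score = 0)
  over <- list(...)
  ref[names(over)] <- over
  ref
}

# Reference exposure for contrasts: the natural null exposure per kind.
reference_exposure <- function(kind) {
  switch(kind,
         sustained_min_map = 75,
         cumulative_min_map = 75,
         abs_time_below = 0,
         rel_time_below = 0)
}

default_effect_points <- function(kind) {
  switch(kind,
         sustained_min_map = c(50, 65, 75),
         cumulative_min_map = c(50, 65, 75),
         abs_time_below = c(5, 10),
         rel_time_below = c(0.05, 0.10))
}

#' Fit the selected definition's model on the estimation half
#'
#' Rebuilds the model matrix on the estimation half with the same settings
#' (spline dfs, winsorization rule, trim fraction) used during shaping and
#' fits the outcome model. Errors with "split leakage" if any estimation
#' patient was part of the shaping half.
#'
#' @param half Estimation half of the cohort table.
#' @param selection An `ioh_selection` from [shape_outcome()].
#' @param definition Definition to fit; defaults to `selection$best`.
#' @return An `ioh_fit` carrying the model matrix as attribute
#'   `model_matrix`.
#' @export
fit_best <- function(half, selection, definition = NULL) {
  stopifnot(inherits(selection, "ioh_selection"))
  if (length(intersect(half$patient_id, selection$shaping_ids)))
    stop("split leakage: estimation half overlaps the shaping half",
         call. = FALSE)
  definition <- definition %||% selection$best
  if (!definition %in% names(half))
    stop(sprintf("definition '%s' missing from estimation-cohort features",
                 definition), call. = FALSE)
  mm <- build_model_matrix(half, definition, selection$outcome,
                           selection$scheme$settings, selection$registry)
  fit <- fit_model(mm)
  attr(fit, "model_matrix") <- mm
  fit
}

# Linear predictor and delta-method SE for a design row (or matrix of rows).
lp_with_se <- function(fit, rows) {
  nm <- names(fit$coefficients)
  if (!is.null(nm) && all(nzchar(nm)) && all(nm %in% colnames(rows)))
    rows <- rows[, nm, drop = FALSE]
  eta <- drop(rows %*% fit$coefficients)
  se <- sqrt(rowSums((rows %*% fit$vcov) * rows))
  list(eta = eta, se = se)
}

#' Adjusted effect curve for the reference patient
#'
#' Predicted outcome across a grid of exposure values, holding all
#' adjustment covariates at the reference patient: probability of 30-day
#' death for mortality, back-transformed (exponentiated) length of stay for
#' metric outcomes. Confidence intervals are delta-method intervals on the
#' linear predictor, transformed to the reporting scale. Grid values beyond
#' the winsorization cap are clipped with a warning.
#'
#' @param fit An `ioh_fit` from [fit_best()].
#' @param ref A [reference_patient()].
#' @param exposure Numeric grid of exposure values; `NULL` uses an
#'   equispaced grid over the fitted (winsorized) range.
#' @param level Confidence level, default 0.95.
#' @return Data frame `exposure`, `fit`, `lo`, `hi` (reporting scale) plus
#'   `lp`, `se`.
#' @export
effect_curve <- function(fit, ref = reference_patient(), exposure = NULL,
                         level = 0.95) {
  mm <- attr(fit, "model_matrix")
  if (is.null(mm)) stop("fit carries no model matrix; use fit_best()")
  bm <- mm$meta$blocks$ioh
  if (is.null(exposure)) {
    hi <- bm$cap %||% bm$boundary[2]
    exposure <- seq(bm$boundary[1], hi, length.out = 50)
  }
  cap <- bm$cap %||% Inf
  if (any(exposure > cap)) {
    warning("exposure grid clipped at the winsorization cap")
    exposure <- pmin(exposure, cap)
  }
  rows <- t(vapply(exposure, function(v) design_row(mm, v, ref),
                   numeric(ncol(mm$X))))
  ls <- lp_with_se(fit, rows)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  trans <- if (fit$binary) stats::plogis else exp
  data.frame(exposure = exposure,
             fit = trans(ls$eta),
             lo = trans(ls$eta - zq * ls$se),
             hi = trans(ls$eta + zq * ls$se),
             lp = ls$eta, se = ls$se)
}

#' Effect sizes at clinically relevant exposure points
#'
#' Contrasts of each evaluation point against the reference exposure (MAP 75
#' mmHg for sustained/cumulative lowest-MAP definitions; zero time below the
#' threshold for time-below definitions): odds ratios for mortality, ratios
#' of back-transformed length of stay for metric outcomes, with delta-method
#' confidence intervals. Default points are MAP 50, 65 and 75 mmHg, 5 and 10
#' minutes, or 5% and 10% of anesthesia time, by definition kind.
#'
#' @param fit An `ioh_fit` from [fit_best()].
#' @param ref A [reference_patient()].
#' @param points Evaluation points; `NULL` uses the kind's defaults.
#' @param ref_exposure Reference exposure; `NULL` uses the kind's default.
#' @param level Confidence level.
#' @return Data frame with `point`, `ref_exposure`, `contrast`, `lo`, `hi`,
#'   `scale` (`"odds ratio"` or `"LOS ratio"`) and `extrapolated` (point
#'   outside the observed/winsorized range).
#' @export
effect_at_points <- function(fit, ref = reference_patient(), points = NULL,
                             ref_exposure = NULL, level = 0.95) {
  mm <- attr(fit, "model_matrix")
  if (is.null(mm)) stop("fit carries no model matrix; use fit_best()")
  kind <- mm$meta$kind
  points <- points %||% default_effect_points(kind)
  ref_exposure <- ref_exposure %||% reference_exposure(kind)
  bm <- mm$meta$blocks$ioh
  cap <- bm$cap %||% bm$boundary[2]
  row_ref <- design_row(mm, ref_exposure, ref)
  rows <- t(vapply(points, function(v) design_row(mm, min(v, cap), ref),
                   numeric(ncol(mm$X))))
  diff_rows <- sweep(rows, 2, row_ref)
  ls <- lp_with_se(fit, diff_rows)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(point = points,
             ref_exposure = ref_exposure,
             contrast = exp(ls$eta),
             lo = exp(ls$eta - zq * ls$se),
             hi = exp(ls$eta + zq * ls$se),
             scale = if (fit$binary) "odds ratio" else "LOS ratio",
             extrapolated = points < bm$boundary[1] | points > cap)
}

#' Variable contributions to cross-validated model performance
#'
#' For each variable group in the full multivariable model (the IOH block
#' including its zero indicator, then sex, age, BMI, duration of surgery,
#' time to surgery, specialty, ASA, comorbidity), refits the model without
#' that group under fold partitions shared across all refits and reports the
#' increase in cross-validated Brier score or MSE relative to the full
#' model.
#'
#' @param half Estimation half of the cohort table.
#' @param selection The shaping-stage `ioh_selection`.
#' @param definition Definition to analyse; defaults to the selected best.
#' @param k,reps,seed CV scheme; defaults mirror the selection scheme.
#' @return Data frame `variable`, `cv_full`, `cv_without`, `delta`, sorted
#'   by decreasing `delta`.
#' @export
variable_contribution <- function(half, selection, definition = NULL,
                                  k = NULL, reps = NULL, seed = NULL) {
  stopifnot(inherits(selection, "ioh_selection"))
  definition <- definition %||% selection$best
  k <- k %||% selection$scheme$k
  reps <- reps %||% selection$scheme$reps
  seed <- seed %||% selection$scheme$seed
  mm <- build_model_matrix(half, definition, selection$outcome,
                           selection$scheme$settings, selection$registry)
  folds <- make_folds(mm$y, k, reps, seed,
                      stratify = mm$binary)
  full <- cv_engine(mm$X, mm$y, mm$binary, folds, k)
  vars <- setdiff(names(mm$groups), "intercept")
  rows <- lapply(vars, function(v) {
    Xr <- mm$X[, -mm$groups[[v]], drop = FALSE]
    red <- cv_engine(Xr, mm$y, mm$binary, folds, k)
    data.frame(variable = v, cv_full = full$mean, cv_without = red$mean,
               delta = red$mean - full$mean)
  })
  out <- do.call(rbind, rows)
  out[order(-out$delta), ]
}

#' Sensitivity analysis of the shaping-stage selection
#'
#' Re-runs the shaping-stage selection under variant settings -- alternative
#' upper trim fractions for length-of-stay outcomes (1.5%, 2%) and/or 4
#' spline degrees of freedom for the IOH definitions -- and reports how the
#' candidate ranking moves.
#'
#' @param half Shaping half of the cohort table.
#' @param outcome Outcome name.
#' @param variants Named list of variants, each a list with any of
#'   `trim_fraction`, `ioh_df`. Default: both trim variants and the 4-df
#'   variant.
#' @param registry,k,reps,seed,settings As in [shape_outcome()].
#' @return List with `baseline` (an `ioh_selection`), `variants` (named list
#'   of selections) and `rank_changes` (data frame comparing ranks).
#' @export
sensitivity_analysis <- function(half, outcome,
                                 variants = list(
                                   trim_1.5 = list(trim_fraction = 0.015),
                                   trim_2 = list(trim_fraction = 0.02),
                                   ioh_df4 = list(ioh_df = 4)),
                                 registry = ioh_registry(), k = 10,
                                 reps = 40, seed = 1L,
                                 settings = model_settings()) {
  allowed <- c("trim_fraction", "ioh_df")
  for (v in names(variants)) {
    bad <- setdiff(names(variants[[v]]), allowed)
    if (length(bad))
      stop(sprintf("unknown variant key '%s' in variant '%s'", bad[1], v),
           call. = FALSE)
  }
  baseline <- shape_outcome(half, outcome, registry, k, reps, seed, settings)
  fits <- lapply(variants, function(vv) {
    s <- settings
    s[names(vv)] <- vv
    shape_outcome(half, outcome, registry, k, reps, seed, s)
  })
  rank_of <- function(sel) {
    stats::setNames(sel$table$rank, sel$table$definition)[registry$name]
  }
  changes <- data.frame(definition = registry$name,
                        baseline = unname(rank_of(baseline)))
  for (v in names(fits)) changes[[v]] <- unname(rank_of(fits[[v]]))
  list(baseline = baseline, variants = fits, rank_changes = changes)
}
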