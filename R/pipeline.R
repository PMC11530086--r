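# End-to-end orchestration: simulate -> clean -> features -> split ->
# shaping-stage selection (x3 outcomes) -> estimation stage (x3) -> report,
# with a reproducibility manifest.

#' Configuration for a full pipeline run
#'
#' @param n_patients Cohort size when simulating (ignored if `input_dir`
#'   points at existing CSVs).
#' @param seed Master seed; the split and CV seeds are derived from it.
#' @param registry_choice `"tables_24"`, `"methods_22"`, or `"custom"` (then
#'   supply `registry`).
#' @param registry Custom registry data frame (for `registry_choice =
#'   "custom"`).
#' @param k,reps Cross-validation scheme.
#' @param trim_fraction,ioh_df,df3,df2,winsor_p Modeling settings (see
#'   [model_settings()]).
#' @param outcomes Outcomes to run.
#' @param truth A [truth_config()] for the simulation; `NULL` builds one
#'   from `n_patients` and `seed`.
#' @param input_dir Optional directory of cohort CSVs (see [read_cohort()]);
#'   skips simulation.
#' @param out_dir Output directory for artifacts; `NULL` disables writing.
#' @param variants Sensitivity variants (see [sensitivity_analysis()]), or
#'   `NULL` to skip.
#' @return A `run_config` list.
#' @export
run_config <- function(n_patients = 2000, seed = 1L,
                       registry_choice = c("tables_24", "methods_22",
                                           "custom"),
                       registry = NULL, k = 10, reps = 40,
                       trim_fraction = 0.01, ioh_df = 3, df3 = 3, df2 = 2,
                       winsor_p = 0.99,
                       outcomes = c("mortality", "hlos", "pacu"),
                       truth = NULL, input_dir = NULL, out_dir = NULL,
                       variants = NULL) {
  registry_choice <- match.arg(registry_choice)
  if (registry_choice == "custom" && is.null(registry))
    stop("registry_choice = 'custom' requires a registry data frame")
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 registry_choice = registry_choice, registry = registry,
                 k = k, reps = reps, trim_fraction = trim_fraction,
                 ioh_df = ioh_df, df3 = df3, df2 = df2,
                 winsor_p = winsor_p, outcomes = outcomes,
                 truth = truth, input_dir = input_dir, out_dir = out_dir,
                 variants = variants),
            class = "run_config")
}

config_registry <- function(config) {
  switch(config$registry_choice,
         tables_24 = ioh_registry("tables_24"),
         methods_22 = ioh_registry("methods_22"),
         custom = config$registry)
}

config_fingerprint <- function(config) {
  ser <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                          auto_unbox = TRUE, digits = NA, force = TRUE,
                          null = "null")
  config_hash(as.character(ser))
}

#' Run the full study replica end to end
#'
#' Simulates (or loads) a cohort, cleans and grids the blood-pressure
#' series, computes every registry definition, splits the cohort into
#' shaping and estimation halves, runs the shaping-stage selection for each
#' outcome, fits the winning definition on the estimation half with effect
#' sizes and variable contributions, and writes JSON artifacts plus a
#' manifest. Rerunning with an identical configuration reproduces every
#' numeric output.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return An `ioh_run`: list with `selection`, `estimation` (per outcome:
#'   fit summary, effect sizes, contributions), `attrition`, `split`,
#'   `manifest`, and the feature table.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  registry <- config_registry(config)
  settings <- model_settings(ioh_df = config$ioh_df, df3 = config$df3,
                             df2 = config$df2, winsor_p = config$winsor_p,
                             trim_fraction = config$trim_fraction)

  say("stage simulate")
  cohort <- stage("simulate", {
    if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else {
      tc <- config$truth %||% truth_config(config$n_patients,
                                           seed = config$seed)
      generate_cohort(tc)
    }
  })

  say("stage features (clean + grid + definitions)")
  tab <- stage("features", cohort_features(cohort, registry))

  say("stage split")
  split <- stage("split", split_cohort(tab, seed = child_seed(config$seed,
                                                              77L)))
  shaping <- cohort_half(tab, split, "shaping")
  estimation <- cohort_half(tab, split, "estimation")

  selections <- list()
  estimates <- list()
  for (oc in config$outcomes) {
    say("stage shape: %s", oc)
    sel <- stage(paste0("shape:", oc),
                 shape_outcome(shaping, oc, registry, k = config$k,
                               reps = config$reps,
                               seed = child_seed(config$seed, 177L),
                               settings = settings))
    selections[[oc]] <- sel
    say("stage estimate: %s (best = %s)", oc, sel$best)
    est <- stage(paste0("estimate:", oc), {
      fit <- fit_best(estimation, sel)
      list(fit = fit,
           effects = effect_at_points(fit),
           curve = effect_curve(fit),
           contribution = variable_contribution(estimation, sel),
           hl = if (fit$binary)
             hosmer_lemeshow(fit, attr(fit, "model_matrix")) else NULL)
    })
    estimates[[oc]] <- est
  }

  manifest <- list(config_hash = config_fingerprint(config),
                   seed = config$seed,
                   n_patients = nrow(tab),
                   registry = config$registry_choice,
                   k = config$k, reps = config$reps,
                   outcomes = config$outcomes,
                   package_version = as.character(
                     utils::packageVersion("iohdef")))

  run <- structure(list(selection = selections, estimation = estimates,
                        attrition = attr(tab, "attrition"),
                        cleaning = attr(tab, "cleaning"),
                        split = split, features = tab,
                        manifest = manifest),
                   class = "ioh_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# Serialize the numeric artifacts of a run as JSON files.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", null = "null")
  for (oc in names(run$selection)) {
    sel <- run$selection[[oc]]
    wj(list(outcome = oc, best = sel$best, table = sel$table,
            confidence_set = sel$confidence_set,
            scheme = sel$scheme[c("k", "reps", "seed")]),
       sprintf("selection_%s.json", oc))
    est <- run$estimation[[oc]]
    wj(list(outcome = oc,
            definition = est$fit$meta$definition,
            coefficients = as.list(est$fit$coefficients),
            aic = est$fit$aic,
            effects = est$effects,
            contribution = est$contribution,
            hl_p = if (!is.null(est$hl)) est$hl$p_value else NULL),
       sprintf("estimate_%s.json", oc))
  }
  wj(run$manifest, "manifest.json")
  wj(run$attrition, "attrition.json")
  invisible(dir)
}

#' @export
print.ioh_run <- function(x, ...) {
  cat("End-to-end IOH definition-selection run\n")
  for (oc in names(x$selection))
    cat(sprintf("  %-9s best = %-12s (score %.7f, confidence set %d)\n",
                oc, x$selection[[oc]]$best, x$selection[[oc]]$table$score[1],
                length(x$selection[[oc]]$confidence_set)))
  invisible(x)
}

#' Small fixture bundle for tests and examples
#'
#' Deterministic, hand-checkable inputs: the worked 8-tick MAP grid, a
#' 60-sample blood-pressure series with one constructed violator per
#' cleaning rule, and a small synthetic cohort with a planted exposure
#' effect.
#'
#' @param seed Seed for the cohort fixture.
#' @param n_patients Cohort fixture size (50--200 is typical).
#' @return List with `worked_grid`, `artifact_series` (plus
#'   `artifact_truth`, the expected per-sample reason codes) and `cohort`.
#' @export
make_fixtures <- function(seed = 42L, n_patients = 100L) {
  worked_grid <- c(80, 80, 70, 65, 62, 62, 66, 75)

  # 60-sample series: 54 clean samples around 120/80 plus one violator per
  # rule. Clean noise is small so rule 6 stays quiet on the clean samples.
  set.seed(20240101L)
  n_clean <- 54L
  sbp <- 120 + round(stats::rnorm(n_clean, 0, 2), 1)
  dbp <- 80 + round(stats::rnorm(n_clean, 0, 1.5), 1)
  viol <- data.frame(
    sbp = c(305, 15, 118, 121, 90, 180),
    dbp = c(80, 8, 3, 230, 88, 120),
    rule = paste0("rule", 1:6))
  pos <- c(9L, 19L, 29L, 39L, 49L, 59L)
  all_sbp <- append_at(sbp, viol$sbp, pos)
  all_dbp <- append_at(dbp, viol$dbp, pos)
  truth <- rep("retained", 60L)
  truth[pos] <- viol$rule
  series <- bp_series("FIX01", seq(0, by = 15, length.out = 60L),
                      sbp = all_sbp, dbp = all_dbp,
                      map = (all_sbp + 2 * all_dbp) / 3)

  cohort <- if (n_patients >= 1)
    generate_cohort(truth_config(n_patients, seed = seed,
                                 beta_mortality = 1.5,
                                 target_mortality = 0.05,
                                 covariate_effects = "zero"))

  list(worked_grid = worked_grid,
       artifact_series = series,
       artifact_truth = truth,
       cohort = cohort)
}

# Insert values at given positions of a vector (positions refer to the
# final vector).
append_at <- function(x, values, positions) {
  out <- rep(NA_real_, length(x) + length(values))
  out[positions] <- values
  out[is.na(out)] <- x
  out
}
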