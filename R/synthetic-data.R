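# Synthetic perioperative cohort generator with known ground truth.
#
# Emulates the statistical structure the downstream analysis assumes: raw
# intraoperative blood-pressure series in two recording dialects (2-minute
# and 15-second), artifact contamination matching the six cleaning rules,
# rectangular hypotensive episodes of controllable depth and duration, and
# outcomes (30-day mortality, hospital and PACU length of stay) generated
# from logistic / log-linear models whose exposure term is routed through a
# chosen "true" IOH definition.

SPECIALTIES <- c("Urology, gynecology, general surgery",
                 "Maxillofacial, ENT, derma",
                 "Orthopedics, trauma",
                 "Neurosurgery",
                 "Non-OR anesthesia, obstetrics",
                 "Robotic surgery")

COV_EFFECT_NAMES <- c("sex_female", "age", "bmi", "duration_surgery",
                      "time_to_surgery", "asa", "comorbidity_score",
                      paste0("specialty_", 2:6))

default_cov_effects <- function() {
  zero <- stats::setNames(rep(0, length(COV_EFFECT_NAMES)), COV_EFFECT_NAMES)
  mort <- zero; hlos <- zero; pacu <- zero
  # Log-odds / log-scale slopes per natural unit (years, mmHg, minutes ...),
  # centered at the reference patient (male, 53 y, BMI 26, 100 min surgery,
  # 1 day to surgery, ASA 2, comorbidity 0).
  mort[c("sex_female", "age", "bmi", "duration_surgery",
         "time_to_surgery", "asa", "comorbidity_score")] <-
    c(-0.2, 0.06, -0.02, 0.004, 0.05, 0.9, 0.25)
  hlos[c("age", "bmi", "duration_surgery", "time_to_surgery",
         "asa", "comorbidity_score")] <-
    c(0.004, 0.002, 0.0025, 0.05, 0.12, 0.05)
  pacu[c("age", "duration_surgery", "asa")] <- c(0.001, 0.002, 0.05)
  list(mortality = mort, hlos = hlos, pacu = pacu)
}

#' Ground-truth configuration for the synthetic cohort generator
#'
#' Collects every knob of the generative model: cohort size, recording
#' dialect mix, artifact contamination, blood-pressure dynamics, hypotensive
#' episode process, the "true" IOH definition through which outcome effects
#' are routed, effect sizes, and the master seed.
#'
#' @param n_patients Number of patients (>= 1).
#' @param dialect_fraction_2min Fraction of patients recorded at 2-minute
#'   spacing (the pre-2017 dialect); the rest are recorded every 15 s.
#' @param artifact_rate Per-sample probability of an injected artifact.
#' @param baseline_map_mean,baseline_map_sd Between-patient distribution of
#'   the baseline MAP (mmHg).
#' @param noise_sd,noise_ar Stationary SD (mmHg) and lag-1 autocorrelation of
#'   the within-patient AR(1) MAP noise.
#' @param episode_rate Expected hypotensive episodes per hour of surgery.
#' @param episode_depth_range,episode_duration_range Uniform ranges for
#'   episode depth (mmHg below baseline) and duration (minutes).
#' @param true_definition Name of the registry definition through which the
#'   outcome effects act (see [ioh_registry()]).
#' @param beta_mortality Log-odds of 30-day death per SD of the standardized
#'   true definition value.
#' @param beta_hlos,beta_pacu Log-scale slopes per SD for hospital and PACU
#'   length of stay.
#' @param covariate_effects List with components `mortality`, `hlos`, `pacu`,
#'   each a named vector of covariate coefficients (see
#'   `iohdef:::COV_EFFECT_NAMES`); `NULL` uses modest defaults, `"zero"`
#'   switches all covariate effects off.
#' @param target_mortality Marginal 30-day mortality the intercept is
#'   calibrated to at `beta_mortality = 0` (default 0.9%, the incidence
#'   reported for large mixed surgical cohorts).
#' @param median_hlos_days,median_pacu_hours Location of the log-normal
#'   length-of-stay outcomes at the reference covariates.
#' @param sigma_hlos,sigma_pacu Residual SDs on the log scale.
#' @param icu_admission_prob Probability of direct postoperative ICU
#'   admission (such patients have no PACU stay).
#' @param death_before_discharge_prob Probability that a 30-day death occurs
#'   before hospital discharge.
#' @param duration_median_min,duration_sdlog,duration_range_min Log-normal
#'   surgery-duration distribution (median in minutes, SD on the log scale)
#'   and its truncation range.
#' @param map_missing_rate Fraction of samples whose MAP channel is missing
#'   and must be derived from sbp/dbp downstream.
#' @param seed Master seed; per-patient substreams are derived from it by
#'   counter-based splitting, so enlarging the cohort never reshuffles
#'   earlier patients.
#' @return A validated `truth_config` object.
#' @export
truth_config <- function(n_patients,
                         dialect_fraction_2min = 0.4,
                         artifact_rate = 0.005,
                         baseline_map_mean = 86,
                         baseline_map_sd = 7,
                         noise_sd = 4,
                         noise_ar = 0.9,
                         episode_rate = 1.5,
                         episode_depth_range = c(10, 35),
                         episode_duration_range = c(1, 10),
                         true_definition = "rel_t_lt80",
                         beta_mortality = 0.3,
                         beta_hlos = 0.08,
                         beta_pacu = 0.08,
                         covariate_effects = NULL,
                         target_mortality = 0.009,
                         median_hlos_days = 5.1,
                         median_pacu_hours = 2.1,
                         sigma_hlos = 0.8,
                         sigma_pacu = 0.4,
                         icu_admission_prob = 0.13,
                         death_before_discharge_prob = 0.9,
                         duration_median_min = 100,
                         duration_sdlog = 0.55,
                         duration_range_min = c(20, 480),
                         map_missing_rate = 0.02,
                         seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 1)
    stop_field("n_patients", "must be a single number >= 1")
  assert_fraction(dialect_fraction_2min, "dialect_fraction_2min")
  assert_fraction(artifact_rate, "artifact_rate")
  assert_fraction(icu_admission_prob, "icu_admission_prob")
  assert_fraction(death_before_discharge_prob, "death_before_discharge_prob")
  assert_fraction(target_mortality, "target_mortality")
  assert_fraction(map_missing_rate, "map_missing_rate")
  assert_positive(baseline_map_mean, "baseline_map_mean")
  assert_positive(duration_median_min, "duration_median_min")
  if (length(episode_duration_range) != 2L || any(episode_duration_range <= 0))
    stop_field("episode_duration_range", "must be two positive minutes")
  if (length(episode_depth_range) != 2L || any(episode_depth_range < 0))
    stop_field("episode_depth_range", "must be two non-negative mmHg values")
  if (episode_rate < 0) stop_field("episode_rate", "must be non-negative")
  ioh_definition(true_definition)  # errors on unknown names
  if (identical(covariate_effects, "zero")) {
    covariate_effects <- lapply(default_cov_effects(), function(v) 0 * v)
  } else if (is.null(covariate_effects)) {
    covariate_effects <- default_cov_effects()
  } else {
    stopifnot(all(c("mortality", "hlos", "pacu") %in%
                    names(covariate_effects)))
  }
  structure(list(n_patients = as.integer(n_patients),
                 dialect_fraction_2min = dialect_fraction_2min,
                 artifact_rate = artifact_rate,
                 baseline_map_mean = baseline_map_mean,
                 baseline_map_sd = baseline_map_sd,
                 noise_sd = noise_sd, noise_ar = noise_ar,
                 episode_rate = episode_rate,
                 episode_depth_range = episode_depth_range,
                 episode_duration_range = episode_duration_range,
                 true_definition = true_definition,
                 beta_mortality = beta_mortality,
                 beta_hlos = beta_hlos, beta_pacu = beta_pacu,
                 covariate_effects = covariate_effects,
                 target_mortality = target_mortality,
                 median_hlos_days = median_hlos_days,
                 median_pacu_hours = median_pacu_hours,
                 sigma_hlos = sigma_hlos, sigma_pacu = sigma_pacu,
                 icu_admission_prob = icu_admission_prob,
                 death_before_discharge_prob = death_before_discharge_prob,
                 duration_median_min = duration_median_min,
                 duration_sdlog = duration_sdlog,
                 duration_range_min = duration_range_min,
                 map_missing_rate = map_missing_rate,
                 seed = as.integer(seed)),
            class = "truth_config")
}

# Draw one patient's covariates from marginals loosely matched to a large
# mixed surgical cohort (age median ~53, BMI ~25.7, mostly ASA 1-2).
draw_covariates <- function(config) {
  sex <- if (stats::runif(1) < 0.566) "female" else "male"
  age <- Inf
  while (age < 18 || age > 95) age <- stats::rnorm(1, 52.5, 19)
  bmi <- stats::rlnorm(1, log(25.7), 0.19)
  dur <- Inf
  while (dur < config$duration_range_min[1] ||
         dur > config$duration_range_min[2])
    dur <- stats::rlnorm(1, log(config$duration_median_min),
                         config$duration_sdlog)
  tts <- stats::rlnorm(1, log(1.0), 0.36)
  specialty <- sample(SPECIALTIES, 1,
                      prob = c(0.366, 0.144, 0.264, 0.055, 0.152, 0.019))
  asa <- sample(1:4, 1, prob = c(0.297, 0.455, 0.228, 0.020))
  comorb <- if (stats::runif(1) < 0.55) 0 else stats::rgeom(1, 0.45) + 1
  list(sex = sex, age = age, bmi = bmi, duration_surgery = dur,
       time_to_surgery = tts, specialty = specialty, asa = asa,
       comorbidity_score = comorb)
}

#' Generate one patient's raw blood-pressure series
#'
#' MAP follows a patient-specific constant baseline plus AR(1) noise, with
#' rectangular hypotensive episodes subtracted; systolic and diastolic
#' channels are reconstructed around MAP via a patient-specific pulse
#' pressure. Samples are emitted on the recording dialect's grid (every 120 s
#' before the 15-second era, every 15 s after). Injected artifacts are
#' flagged in a hidden truth channel (`is_artifact`), one of the six cleaning
#' rules being violated per artifact (chosen uniformly), so the cleaning
#' module's sensitivity is measurable.
#'
#' @param patient_params List with at least `duration_surgery` (minutes) and
#'   optionally `baseline_map` (mmHg).
#' @param dialect `"15s"` or `"2min"`.
#' @param seed Integer seed for this patient's stream.
#' @param config A [truth_config()] supplying dynamics parameters.
#' @return List with `series` (a [bp_series()] whose samples carry an
#'   `is_artifact` truth column), `true_grid` (the artifact-free 15-s MAP
#'   vector) and `n_artifacts`.
#' @export
generate_bp_series <- function(patient_params, dialect = "15s",
                               seed = 1L, config = truth_config(1)) {
  if (!dialect %in% c("15s", "2min"))
    stop("dialect must be '15s' or '2min'")
  dur <- patient_params$duration_surgery
  if (is.null(dur) || !is.finite(dur) || dur <= 0)
    stop("duration_surgery must be positive", call. = FALSE)
  set.seed(seed)
  baseline <- patient_params$baseline_map %||%
    stats::rnorm(1, config$baseline_map_mean, config$baseline_map_sd)
  n_t <- floor(dur * 60 / 15) + 1L
  t_grid <- seq(0, by = 15, length.out = n_t)

  innov_sd <- config$noise_sd * sqrt(1 - config$noise_ar^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n_t, 0, innov_sd),
                                    config$noise_ar, method = "recursive"))
  map_true <- baseline + noise

  n_epi <- stats::rpois(1, config$episode_rate * dur / 60)
  if (n_epi > 0) {
    for (e in seq_len(n_epi)) {
      e_dur <- stats::runif(1, config$episode_duration_range[1],
                            config$episode_duration_range[2])
      e_depth <- stats::runif(1, config$episode_depth_range[1],
                              config$episode_depth_range[2])
      e_start <- stats::runif(1, 0, max(0, dur - e_dur))
      idx <- which(t_grid >= e_start * 60 & t_grid < (e_start + e_dur) * 60)
      map_true[idx] <- map_true[idx] - e_depth
    }
  }
  map_true <- pmax(map_true, 30)

  pp <- stats::rnorm(1, 45, 8)
  pp <- max(pp, 20)
  pp_s <- pmax(pp + stats::rnorm(n_t, 0, 2), 15)
  sbp <- map_true + 2 / 3 * pp_s
  dbp <- map_true - 1 / 3 * pp_s
  map_rec <- map_true

  keep <- if (dialect == "2min") seq(1L, n_t, by = 8L) else seq_len(n_t)
  if (length(keep) < 2L) keep <- c(1L, n_t)

  ns <- length(keep)
  sbp <- sbp[keep]; dbp <- dbp[keep]; map_rec <- map_rec[keep]
  is_art <- stats::runif(ns) < config$artifact_rate
  if (any(is_art)) {
    for (i in which(is_art)) {
      rule <- sample(1:6, 1)
      if (rule == 1) sbp[i] <- stats::runif(1, 300, 350)
      else if (rule == 2) sbp[i] <- stats::runif(1, 5, 20)
      else if (rule == 3) dbp[i] <- stats::runif(1, 0, 5)
      else if (rule == 4) dbp[i] <- stats::runif(1, 225, 280)
      else if (rule == 5) sbp[i] <- dbp[i] + stats::runif(1, 0, 5)
      else {
        shift <- sample(c(-1, 1), 1) * stats::runif(1, 45, 70)
        sbp[i] <- min(max(sbp[i] + shift, 25), 295)
        dbp[i] <- min(max(dbp[i] + shift, 8), 220)
        map_rec[i] <- (sbp[i] + 2 * dbp[i]) / 3
      }
      if (rule != 6) map_rec[i] <- (sbp[i] + 2 * dbp[i]) / 3
    }
  }
  map_obs <- map_rec
  miss <- stats::runif(ns) < config$map_missing_rate
  map_obs[miss] <- NA_real_

  series <- bp_series(patient_params$patient_id %||% NA, t_grid[keep],
                      sbp = sbp, dbp = dbp, map = map_obs)
  series$samples$is_artifact <- is_art
  list(series = series, true_grid = map_true, n_artifacts = sum(is_art))
}

#' Generate a synthetic perioperative cohort with known ground truth
#'
#' Draws covariates, raw blood-pressure series and outcomes for
#' `config$n_patients` patients. The true exposure is the configured IOH
#' definition evaluated on each patient's artifact-free 15-second MAP grid;
#' it is standardized across the cohort and enters the outcome models with
#' the configured slopes. The mortality intercept is calibrated so that the
#' covariate-only model (exposure slope zero) has marginal prevalence
#' `target_mortality`; raising `beta_mortality` therefore raises prevalence.
#'
#' @param config A [truth_config()].
#' @return An `ioh_cohort`: list with `covariates` and `outcomes` data
#'   frames, `bp` (list of raw [bp_series()] per patient), `truth` (per
#'   patient: true exposure value, standardized value, linear predictors and
#'   event probabilities) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  n <- config$n_patients
  def <- ioh_definition(config$true_definition)

  cov_rows <- vector("list", n)
  bp <- vector("list", n)
  true_val <- numeric(n)
  u_mort <- numeric(n); u_dbd <- numeric(n); u_icu <- numeric(n)
  z_hlos <- numeric(n); z_pacu <- numeric(n)
  dialect2 <- logical(n)

  for (i in seq_len(n)) {
    set.seed(child_seed(config$seed, i))
    cv <- draw_covariates(config)
    cv$patient_id <- sprintf("P%05d", i)
    dialect2[i] <- stats::runif(1) < config$dialect_fraction_2min
    bp_seed <- child_seed(config$seed, i + 500000L)
    gen <- generate_bp_series(cv, dialect = if (dialect2[i]) "2min" else "15s",
                              seed = bp_seed, config = config)
    set.seed(child_seed(config$seed, i + 1000000L))
    u_mort[i] <- stats::runif(1)
    u_dbd[i] <- stats::runif(1)
    u_icu[i] <- stats::runif(1)
    z_hlos[i] <- stats::rnorm(1)
    z_pacu[i] <- stats::rnorm(1)
    cov_rows[[i]] <- cv
    bp[[i]] <- gen$series
    true_val[i] <- switch(def$kind,
      sustained_min_map  = as.numeric(lowest_sustained_map(gen$true_grid,
                                                           def$parameter)),
      cumulative_min_map = as.numeric(lowest_cumulative_map(gen$true_grid,
                                                            def$parameter)),
      abs_time_below     = time_below(gen$true_grid, def$parameter),
      rel_time_below     = as.numeric(relative_time_below(gen$true_grid,
                                                          def$parameter)))
  }

  covariates <- data.frame(
    patient_id = vapply(cov_rows, `[[`, character(1), "patient_id"),
    sex = vapply(cov_rows, `[[`, character(1), "sex"),
    age = vapply(cov_rows, `[[`, numeric(1), "age"),
    bmi = vapply(cov_rows, `[[`, numeric(1), "bmi"),
    duration_surgery = vapply(cov_rows, `[[`, numeric(1), "duration_surgery"),
    time_to_surgery = vapply(cov_rows, `[[`, numeric(1), "time_to_surgery"),
    specialty = vapply(cov_rows, `[[`, character(1), "specialty"),
    asa = vapply(cov_rows, function(x) as.integer(x$asa), integer(1)),
    comorbidity_score = vapply(cov_rows, `[[`, numeric(1),
                               "comorbidity_score"),
    dialect = ifelse(dialect2, "2min", "15s"),
    stringsAsFactors = FALSE)

  sdv <- stats::sd(true_val)
  z <- if (is.na(sdv) || sdv == 0) rep(0, n)
       else (true_val - mean(true_val)) / sdv

  lp_cov <- function(eff) {
    spec_idx <- match(covariates$specialty, SPECIALTIES)
    spec_eff <- c(0, eff[paste0("specialty_", 2:6)])[spec_idx]
    eff[["sex_female"]] * (covariates$sex == "female") +
      eff[["age"]] * (covariates$age - 53) +
      eff[["bmi"]] * (covariates$bmi - 26) +
      eff[["duration_surgery"]] * (covariates$duration_surgery - 100) +
      eff[["time_to_surgery"]] * (covariates$time_to_surgery - 1) +
      eff[["asa"]] * (covariates$asa - 2) +
      eff[["comorbidity_score"]] * covariates$comorbidity_score +
      spec_eff
  }
  lpc_m <- lp_cov(config$covariate_effects$mortality)
  lpc_h <- lp_cov(config$covariate_effects$hlos)
  lpc_p <- lp_cov(config$covariate_effects$pacu)

  # Intercept calibrated at zero exposure slope; see roxygen note.
  alpha <- calibrate_logit_intercept(lpc_m, config$target_mortality)
  lp_m <- alpha + config$beta_mortality * z + lpc_m
  p_mort <- stats::plogis(lp_m)
  died_30d <- u_mort < p_mort
  died_before_discharge <- died_30d &
    (u_dbd < config$death_before_discharge_prob)

  lp_h <- log(config$median_hlos_days) + config$beta_hlos * z + lpc_h
  hlos <- exp(lp_h + config$sigma_hlos * z_hlos)
  lp_p <- log(config$median_pacu_hours) + config$beta_pacu * z + lpc_p
  pacu <- exp(lp_p + config$sigma_pacu * z_pacu)
  icu_direct <- u_icu < config$icu_admission_prob
  pacu[icu_direct] <- NA_real_

  outcomes <- data.frame(patient_id = covariates$patient_id,
                         died_30d = died_30d,
                         hlos = hlos,
                         pacu_los = pacu,
                         icu_direct = icu_direct,
                         died_before_discharge = died_before_discharge,
                         stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = covariates$patient_id,
                      true_definition = config$true_definition,
                      true_value = true_val,
                      z = z,
                      lp_mortality = lp_m,
                      p_mortality = p_mort,
                      lp_hlos = lp_h,
                      lp_pacu = lp_p,
                      stringsAsFactors = FALSE)
  structure(list(covariates = covariates, outcomes = outcomes, bp = bp,
                 truth = truth, config = config,
                 mortality_intercept = alpha),
            class = "ioh_cohort")
}

# Solve the logistic intercept so the covariate-only model hits the target
# marginal prevalence.
calibrate_logit_intercept <- function(lp_cov, target) {
  f <- function(a) mean(stats::plogis(a + lp_cov)) - target
  stats::uniroot(f, c(-30, 10), tol = 1e-10)$root
}

#' @export
print.ioh_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic perioperative cohort: %d patients, ",
                     "true exposure '%s'\n"),
              nrow(x$covariates), x$config$true_definition))
  cat(sprintf("  30-day mortality %.2f%%, median hLOS %.1f d\n",
              100 * mean(x$outcomes$died_30d),
              stats::median(x$outcomes$hlos)))
  invisible(x)
}

#' Export the ground-truth table of a synthetic cohort
#'
#' Writes (or returns) one row per patient with the realized true exposure
#' value, its standardized form and every linear predictor used in outcome
#' generation, plus the generating slopes, enabling parameter-recovery tests.
#'
#' @param cohort An `ioh_cohort` from [generate_cohort()].
#' @param path Optional file path; `.json` writes JSON, anything else CSV
#'   (with the slopes in a JSON sidecar attribute only for JSON output).
#' @return Invisibly, a list with `truth` (data frame) and `betas`.
#' @export
export_truth <- function(cohort, path = NULL) {
  stopifnot(inherits(cohort, "ioh_cohort"))
  out <- list(truth = cohort$truth,
              betas = list(beta_mortality = cohort$config$beta_mortality,
                           beta_hlos = cohort$config$beta_hlos,
                           beta_pacu = cohort$config$beta_pacu,
                           mortality_intercept = cohort$mortality_intercept))
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE)
    } else {
      utils::write.csv(cohort$truth, path, row.names = FALSE)
    }
  }
  invisible(out)
}

#' Write a cohort's raw tables to CSV
#'
#' Emits `vitals.csv` (patient_id, timestamp_s, sbp, dbp, map), plus
#' `covariates.csv` and `outcomes.csv`, under `dir`. The hidden artifact
#' truth channel is deliberately not exported with the vitals.
#'
#' @param cohort An `ioh_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vit <- do.call(rbind, lapply(cohort$bp, function(s) {
    data.frame(patient_id = s$patient_id,
               timestamp_s = s$samples$time_s,
               sbp = s$samples$sbp, dbp = s$samples$dbp,
               map = s$samples$map)
  }))
  paths <- file.path(dir, c("vitals.csv", "covariates.csv", "outcomes.csv"))
  utils::write.csv(vit, paths[1], row.names = FALSE)
  utils::write.csv(cohort$covariates, paths[2], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `vitals.csv`, `covariates.csv`,
#'   `outcomes.csv`.
#' @return An `ioh_cohort` without truth record (external data carry none).
#' @export
read_cohort <- function(dir) {
  vit <- utils::read.csv(file.path(dir, "vitals.csv"))
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"))
  outcomes <- utils::read.csv(file.path(dir, "outcomes.csv"))
  bp <- lapply(split(vit, vit$patient_id)[unique(vit$patient_id)],
               function(d) bp_series(d$patient_id[1], d$timestamp_s,
                                     d$sbp, d$dbp, d$map))
  bp <- bp[covariates$patient_id]
  structure(list(covariates = covariates, outcomes = outcomes,
                 bp = unname(bp), truth = NULL, config = NULL),
            class = "ioh_cohort")
}
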