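# Synthetic cohort generator: validation, determinism, calibration and
# self-consistency of the ground truth.

test_that("invalid configuration fields are rejected by name", {
  expect_error(truth_config(0), "n_patients")
  expect_error(truth_config(10, artifact_rate = 1.5), "artifact_rate")
  expect_error(truth_config(10, dialect_fraction_2min = -0.1),
               "dialect_fraction_2min")
  expect_error(truth_config(10, episode_duration_range = c(0, 5)),
               "episode_duration_range")
  expect_error(truth_config(10, true_definition = "bogus"), "unknown")
})

test_that("generation is deterministic and stable under cohort growth", {
  c1 <- generate_cohort(short_config(60, seed = 7))
  c2 <- generate_cohort(short_config(60, seed = 7))
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$bp, c2$bp)
  expect_identical(c1$truth, c2$truth)
  # counter-based substreams: the first patients do not reshuffle when the
  # cohort grows
  c3 <- generate_cohort(short_config(80, seed = 7))
  expect_identical(c3$covariates[1:60, ], c1$covariates)
  expect_identical(c3$bp[1:60], c1$bp)
})

test_that("covariate marginals respect their invariants", {
  co <- generate_cohort(short_config(400, seed = 3))
  cv <- co$covariates
  expect_true(all(cv$age >= 18))
  expect_true(all(cv$duration_surgery > 0))
  expect_true(all(cv$asa %in% 1:4))
  expect_true(all(cv$comorbidity_score >= 0))
  expect_true(all(cv$specialty %in% iohdef:::SPECIALTIES))
  expect_false(anyNA(cv))
  expect_false(any(duplicated(cv$patient_id)))
  # both recording dialects appear and have the nominal spacing
  sp <- vapply(co$bp, function(s) diff(s$samples$time_s[1:2]), numeric(1))
  expect_setequal(unique(sp), c(15, 120))
})

test_that("BP series carry the dialect grid, episodes and artifact truth", {
  pp <- list(patient_id = "X", duration_surgery = 60)
  g <- generate_bp_series(pp, dialect = "2min", seed = 1,
                          config = truth_config(1, artifact_rate = 0))
  # 60 min at 120-s spacing: floor(60*60/120)+1 = 31 samples
  expect_equal(nrow(g$series$samples), 31)
  expect_equal(unique(diff(g$series$samples$time_s)), 120)
  expect_equal(g$n_artifacts, 0)
  expect_error(generate_bp_series(list(duration_surgery = -5)),
               "positive")

  # with no episodes and tight noise no sample drops below 65 mmHg
  cfg <- truth_config(1, episode_rate = 0, baseline_map_mean = 85,
                      baseline_map_sd = 0.1, noise_sd = 3,
                      artifact_rate = 0)
  g2 <- generate_bp_series(list(duration_surgery = 120,
                                baseline_map = 85), seed = 2, config = cfg)
  expect_true(all(g2$true_grid > 65))

  # injected artifacts are flagged in the hidden truth channel
  cfg3 <- truth_config(1, artifact_rate = 0.2)
  g3 <- generate_bp_series(list(duration_surgery = 60), seed = 3,
                           config = cfg3)
  expect_equal(g3$n_artifacts, sum(g3$series$samples$is_artifact))
  expect_gt(g3$n_artifacts, 0)
})

test_that("mortality intercept calibration hits the target prevalence", {
  co <- generate_cohort(truth_config(
    50000, seed = 11, beta_mortality = 0, covariate_effects = "zero",
    target_mortality = 0.01, duration_median_min = 30,
    duration_sdlog = 0.2, artifact_rate = 0))
  prev <- mean(co$outcomes$died_30d)
  # binomial MC error at n = 50,000: sd ~ 4.4e-4
  expect_lt(abs(prev - 0.01), 3.5 * sqrt(0.01 * 0.99 / 50000))
})

test_that("mortality prevalence increases monotonically with the slope", {
  prev <- vapply(c(0, 0.8, 1.6), function(b) {
    co <- generate_cohort(truth_config(
      20000, seed = 19, beta_mortality = b, target_mortality = 0.02,
      duration_median_min = 40, duration_sdlog = 0.3))
    mean(co$outcomes$died_30d)
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("truth record is self-consistent with the exposure pipeline", {
  cfg <- short_config(40, seed = 23, artifact_rate = 0,
                      map_missing_rate = 0, dialect_fraction_2min = 0,
                      episode_depth_range = c(8, 16))
  co <- generate_cohort(cfg)
  tab <- cohort_features(co)
  expect_equal(nrow(tab), 40)
  # artifact-free 15-s records: cleaning removes nothing beyond rule 6,
  # and the recomputed true-definition values match the truth record
  # wherever rule 6 left the series untouched
  agree <- abs(tab$rel_t_lt80 - co$truth$true_value) < 1e-9
  expect_gt(mean(agree), 0.9)
  expect_equal(attr(tab, "cleaning")[["rule1"]], 0L)
})

test_that("export_truth round-trips values and slopes exactly", {
  co <- generate_cohort(short_config(25, seed = 31, beta_mortality = 0.37))
  tmp <- file.path(tempdir(), "truth.json")
  tr <- export_truth(co, tmp)
  expect_equal(nrow(tr$truth), 25)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$betas$beta_mortality, 0.37)
  expect_equal(back$truth$true_value, co$truth$true_value)
  expect_equal(back$truth$lp_mortality, co$truth$lp_mortality)
})

test_that("ICU-direct patients have no PACU stay", {
  co <- generate_cohort(short_config(300, seed = 41,
                                     icu_admission_prob = 0.3))
  oc <- co$outcomes
  expect_true(all(is.na(oc$pacu_los[oc$icu_direct])))
  expect_true(all(!is.na(oc$pacu_los[!oc$icu_direct])))
  expect_true(all(oc$died_30d[oc$died_before_discharge]))
})

test_that("cohort CSV export/import round-trips the analysis inputs", {
  co <- generate_cohort(short_config(15, seed = 51))
  d <- file.path(tempdir(), "cohort_csv")
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$covariates$patient_id, co$covariates$patient_id)
  expect_equal(back$outcomes$died_30d, co$outcomes$died_30d)
  expect_equal(length(back$bp), 15)
  expect_equal(back$bp[[3]]$samples$map, co$bp[[3]]$samples$map,
               tolerance = 1e-12)
})
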