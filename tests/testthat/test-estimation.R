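# Estimation stage: independence enforcement, effect curves and contrasts,
# variable contributions and sensitivity variants.

make_halves <- function(n = 500, seed = 101, ...) {
  co <- generate_cohort(short_config(n, seed = seed,
                                     target_mortality = 0.08,
                                     beta_mortality = 1.2,
                                     death_before_discharge_prob = 0, ...))
  tab <- cohort_features(co)
  sp <- split_cohort(tab, seed = seed + 1)
  list(tab = tab,
       sh = cohort_half(tab, sp, "shaping"),
       es = cohort_half(tab, sp, "estimation"))
}

test_that("estimation refuses overlapping halves and missing definitions", {
  h <- make_halves(300)
  reg <- ioh_registry()[c(6, 24), ]
  sel <- suppressMessages(shape_outcome(h$sh, "mortality", reg, k = 4, reps = 1, seed = 3))
  expect_error(fit_best(h$sh, sel), "split leakage")
  es2 <- h$es
  es2$rel_t_lt80 <- NULL
  sel2 <- sel
  sel2$best <- "rel_t_lt80"
  expect_error(fit_best(es2, sel2), "missing from estimation")
  # refits with identical inputs are identical
  f1 <- fit_best(h$es, sel)
  f2 <- fit_best(h$es, sel)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("effect curves stay inside their own confidence bands", {
  h <- make_halves(600, seed = 111)
  reg <- ioh_registry()[24, , drop = FALSE]   # rel_t_lt80
  sel <- suppressMessages(shape_outcome(h$sh, "mortality", reg, k = 4, reps = 1, seed = 5))
  fit <- fit_best(h$es, sel)
  cur <- effect_curve(fit, exposure = seq(0, 0.8, by = 0.1))
  expect_true(all(cur$fit >= cur$lo & cur$fit <= cur$hi))
  expect_true(all(cur$fit > 0 & cur$fit < 1))
  expect_warning(effect_curve(fit, exposure = c(0.5, 5)), "clipped")

  # metric outcome: the back-transform of linear predictor 0 is 1
  self <- shape_outcome(h$sh, "hlos", reg, k = 4, reps = 1, seed = 5)
  fith <- fit_best(h$es, self)
  curh <- effect_curve(fith, exposure = c(0, 0.2))
  expect_equal(curh$fit, exp(curh$lp), tolerance = 1e-12)
})

test_that("contrasts equal one at the reference exposure", {
  h <- make_halves(500, seed = 121)
  reg <- ioh_registry()[c(1, 24), ]
  for (oc in c("mortality", "hlos")) {
    sel <- suppressMessages(shape_outcome(h$sh, oc, reg, k = 4, reps = 1, seed = 7))
    fit <- fit_best(h$es, sel)
    kind <- attr(fit, "model_matrix")$meta$kind
    ref_x <- iohdef:::reference_exposure(kind)
    eff <- effect_at_points(fit, points = c(ref_x,
                                            iohdef:::default_effect_points(kind)))
    expect_equal(eff$contrast[1], 1, tolerance = 1e-12)
    expect_true(all(eff$lo <= eff$contrast & eff$contrast <= eff$hi))
    expect_equal(unique(eff$scale),
                 if (oc == "mortality") "odds ratio" else "LOS ratio")
  }
})

test_that("a planted duration effect dominates the contribution table", {
  # only duration of surgery drives hLOS (all other effects zero)
  eff <- lapply(iohdef:::default_cov_effects(), function(v) 0 * v)
  eff$hlos["duration_surgery"] <- 0.01
  co <- generate_cohort(short_config(1200, seed = 131, beta_mortality = 0,
                                     beta_hlos = 0, beta_pacu = 0,
                                     covariate_effects = eff,
                                     sigma_hlos = 0.3))
  tab <- cohort_features(co)
  sp <- split_cohort(tab, seed = 132)
  sh <- cohort_half(tab, sp, "shaping")
  es <- cohort_half(tab, sp, "estimation")
  reg <- ioh_registry()[1, , drop = FALSE]
  sel <- shape_outcome(sh, "hlos", reg, k = 5, reps = 2, seed = 9)
  ct <- variable_contribution(es, sel)
  expect_equal(nrow(ct), 9)
  expect_setequal(ct$variable,
                  c("ioh", "sex", "age", "bmi", "duration",
                    "time_to_surgery", "specialty", "asa", "comorbidity"))
  expect_equal(ct$variable[which.max(ct$delta)], "duration")
  # removing uninformative groups barely moves the CV score
  expect_lt(abs(ct$delta[ct$variable == "sex"]), 0.05)
})

test_that("sensitivity variants change settings as specified", {
  h <- make_halves(400, seed = 141)
  reg <- ioh_registry()[c(3, 24), ]
  sa <- sensitivity_analysis(h$sh, "hlos",
                             variants = list(ioh_df4 = list(ioh_df = 4),
                                             trim_2 = list(trim_fraction = 0.02)),
                             registry = reg, k = 4, reps = 1, seed = 11)
  expect_named(sa$variants, c("ioh_df4", "trim_2"))
  expect_equal(nrow(sa$rank_changes), 2)
  # df = 4 variant: the IOH spline block has 4 columns
  fit4 <- fit_best(h$es, sa$variants$ioh_df4, definition = "sust_5min")
  expect_equal(length(attr(fit4, "model_matrix")$groups$ioh), 4)
  # identical variant reproduces the baseline ranking
  sa0 <- sensitivity_analysis(h$sh, "hlos",
                              variants = list(same = list(ioh_df = 3)),
                              registry = reg, k = 4, reps = 1, seed = 11)
  expect_equal(sa0$variants$same$table, sa0$baseline$table)
  expect_error(sensitivity_analysis(h$sh, "hlos",
                                    variants = list(x = list(foo = 1)),
                                    registry = reg, k = 4, reps = 1,
                                    seed = 11),
               "unknown variant key")
})
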