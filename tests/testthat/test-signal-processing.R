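# Artifact cleaning rules, MAP derivation and grid interpolation.

make_series <- function(sbp, dbp, map = (sbp + 2 * dbp) / 3) {
  bp_series("T1", seq(0, by = 15, length.out = length(sbp)),
            sbp = sbp, dbp = dbp, map = map)
}

test_that("each absolute cleaning rule removes exactly its violator", {
  base_s <- rep(120, 21); base_d <- rep(80, 21)
  cases <- list(
    list(i = 5, sbp = 300, dbp = 80, rule = "rule1"),
    list(i = 5, sbp = 20, dbp = 8, rule = "rule2"),
    list(i = 5, sbp = 120, dbp = 5, rule = "rule3"),
    list(i = 5, sbp = 120, dbp = 225, rule = "rule4"),
    list(i = 5, sbp = 120, dbp = 118, rule = "rule5")  # 120 <= 118 + 5
  )
  for (cs in cases) {
    s <- base_s; d <- base_d
    s[cs$i] <- cs$sbp; d[cs$i] <- cs$dbp
    res <- clean_artifacts(make_series(s, d))
    expect_equal(unname(res$report$removed[cs$rule]), 1, info = cs$rule)
    expect_equal(res$report$retained, 20, info = cs$rule)
    expect_equal(res$report$reasons[cs$i], cs$rule)
  }
})

test_that("a sample violating several rules is attributed to the lowest", {
  s <- rep(120, 20); d <- rep(80, 20)
  s[3] <- 15; d[3] <- 14   # violates rule 2 and rule 5
  res <- clean_artifacts(make_series(s, d))
  expect_equal(res$report$reasons[3], "rule2")
})

test_that("rule 6 removes 3-SD outliers computed on rule-1-to-5 survivors", {
  # constant series passes: SD = 0, deviation 0 is not > 0
  res <- clean_artifacts(make_series(rep(120, 20), rep(80, 20)))
  expect_equal(res$report$retained, 20)

  # 19 maps at 90, one at 180: hand-check |180 - mean| > 3 SD
  mp <- c(rep(90, 19), 180)
  expect_true(abs(180 - mean(mp)) > 3 * sd(mp))
  s <- bp_series("T2", seq(0, by = 15, length.out = 20),
                 sbp = mp + 30, dbp = mp - 15, map = mp)
  res2 <- clean_artifacts(s)
  expect_equal(unname(res2$report$removed["rule6"]), 1)
  expect_equal(res2$report$reasons[20], "rule6")

  # the MAP-only variant ignores an sbp-channel outlier
  s3 <- bp_series("T3", seq(0, by = 15, length.out = 20),
                  sbp = c(rep(120, 19), 200), dbp = rep(80, 20),
                  map = rep(95, 20))
  expect_equal(clean_artifacts(s3, "map")$report$retained, 20)
  expect_equal(unname(clean_artifacts(s3, "all")$report$removed["rule6"]), 1)
})

test_that("cleaning is idempotent and order-invariant", {
  fx <- make_fixtures(seed = 5, n_patients = 0)
  r1 <- clean_artifacts(fx$artifact_series)
  r2 <- clean_artifacts(r1$series)
  expect_identical(r1$series$samples[names(r2$series$samples)],
                   r2$series$samples)
  expect_equal(r2$report$retained, r1$report$retained)

  # permuting then re-sorting the input leaves the result unchanged
  set.seed(9)
  perm <- sample(nrow(fx$artifact_series$samples))
  samp <- fx$artifact_series$samples[perm, ]
  samp <- samp[order(samp$time_s), ]
  s_perm <- bp_series("FIX01", samp$time_s, samp$sbp, samp$dbp, samp$map)
  r3 <- clean_artifacts(s_perm)
  expect_equal(r3$report$removed, r1$report$removed)
})

test_that("the 60-sample fixture is cleaned exactly per its truth labels", {
  fx <- make_fixtures(seed = 5, n_patients = 0)
  res <- clean_artifacts(fx$artifact_series)
  expect_identical(res$report$reasons, fx$artifact_truth)
  expect_equal(res$report$retained, 54)
  expect_equal(unname(res$report$removed[paste0("rule", 1:6)]), rep(1L, 6))
})

test_that("an all-artifact series flags the patient for exclusion", {
  s <- make_series(rep(310, 5), rep(80, 5))
  res <- clean_artifacts(s)
  expect_true(res$excluded)
  expect_equal(res$exclusion_reason, "no valid blood pressure")
})

test_that("derive_map applies the standard formula and its precondition", {
  expect_equal(derive_map(120, 60), 80)
  expect_equal(derive_map(150, 75), 100)
  expect_error(derive_map(90, 90), "sbp > dbp")
  # missing MAP channels are completed during cleaning, bad ones dropped
  s <- bp_series("T4", c(0, 15, 30), sbp = c(120, 120, NA),
                 dbp = c(60, 60, NA), map = c(80, NA, NA))
  res <- clean_artifacts(s)
  expect_equal(res$series$samples$map, c(80, 80))
  expect_equal(res$report$reasons[3], "missing_pressure")
})

test_that("interpolation fills 15-s ticks linearly without extrapolation", {
  s <- bp_series("T5", c(0, 120), map = c(60, 68))
  g <- interpolate_to_grid(s)
  expect_equal(g$map, seq(60, 68, by = 1))
  expect_equal(g$time_s, seq(0, 120, by = 15))

  s2 <- bp_series("T6", c(0, 120, 240), map = c(80, 60, 80))
  g2 <- interpolate_to_grid(s2)
  expect_equal(g2$map[g2$time_s == 180], 70)
  # grid values stay within the bracketing measurements
  expect_true(all(g2$map >= 60 & g2$map <= 80))

  # a native 15-s series passes through unchanged
  v <- c(80, 78, 77, 79, 81)
  s3 <- bp_series("T7", seq(0, by = 15, length.out = 5), map = v)
  expect_equal(interpolate_to_grid(s3)$map, v)

  expect_error(interpolate_to_grid(bp_series("T8", 0, map = 80)),
               "fewer than two")
  expect_error(interpolate_to_grid(bp_series("T9", c(0, 600), map = c(8, 9)),
                                   max_gap_s = 120), "gap")
})

test_that("injected rule-violating artifacts are all caught by rules 1-5", {
  cfg <- short_config(30, seed = 77, artifact_rate = 0.05,
                      map_missing_rate = 0)
  co <- generate_cohort(cfg)
  n_checked <- 0L
  for (s in co$bp) {
    res <- clean_artifacts(s)
    d <- s$samples
    # hidden-truth artifacts that violate an absolute rule must all be
    # removed under a rule-1-to-5 reason (100% sensitivity)
    viol <- d$is_artifact &
      (d$sbp >= 300 | d$sbp <= 20 | d$dbp <= 5 | d$dbp >= 225 |
         d$sbp <= d$dbp + 5)
    if (any(viol)) {
      expect_true(all(res$report$reasons[viol] %in% paste0("rule", 1:5)))
      n_checked <- n_checked + sum(viol)
    }
  }
  expect_gt(n_checked, 20)  # the corpus actually exercised the rules
})
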