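# Shaping stage: splits, cross-validation closed forms, ranking rules and
# Akaike-weight confidence sets.

test_that("cohort splits are balanced, exhaustive and seed-deterministic", {
  s10 <- split_cohort(sprintf("P%02d", 1:10), seed = 3)
  expect_equal(sum(s10$half == "shaping"), 5)
  s11 <- split_cohort(sprintf("P%02d", 1:11), seed = 3)
  expect_lte(abs(sum(s11$half == "shaping") - sum(s11$half == "estimation")),
             1)
  expect_identical(split_cohort(1:50, seed = 8), split_cohort(1:50, seed = 8))
  expect_false(identical(split_cohort(1:50, seed = 8)$half,
                         split_cohort(1:50, seed = 9)$half))
  expect_error(split_cohort("P1"), "at least two")
})

test_that("intercept-only CV Brier approaches p(1-p)", {
  set.seed(71)
  n <- 4000
  y <- rbinom(n, 1, 0.5)
  X <- cbind(`(Intercept)` = rep(1, n))
  folds <- iohdef:::make_folds(y, 10, 3, seed = 5)
  cv <- iohdef:::cv_engine(X, y, TRUE, folds, 10)
  expect_equal(cv$mean, 0.25, tolerance = 0.01)

  y2 <- rbinom(n, 1, 0.1)
  cv2 <- iohdef:::cv_engine(X, y2, TRUE,
                            iohdef:::make_folds(y2, 10, 3, seed = 5), 10)
  expect_equal(cv2$mean, mean(y2) * (1 - mean(y2)), tolerance = 0.01)
})

test_that("CV MSE of a noiseless linear model is essentially zero", {
  x <- seq(0, 5, length.out = 200)
  y <- 2 * x
  X <- cbind(1, x = x)
  folds <- iohdef:::make_folds(y, 5, 2, seed = 4, stratify = FALSE)
  cv <- iohdef:::cv_engine(X, y, FALSE, folds, 5)
  expect_lt(cv$mean, 1e-20)
})

test_that("fold partitions are stratified and reproducible", {
  y <- c(rep(1, 20), rep(0, 180))
  f1 <- iohdef:::make_folds(y, 10, 2, seed = 6)
  f2 <- iohdef:::make_folds(y, 10, 2, seed = 6)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_equal(sort(unique(f)), 1:10)
    # stratification: every fold receives exactly two events
    expect_true(all(table(f[y == 1]) == 2))
  }
})

test_that("ranking is by score with parameter-count then order tie-breaks", {
  mk <- function(def, score, np, ord) {
    structure(list(definition = def, outcome = "mortality", score = score,
                   n_params = np, aic = 100, separated = FALSE),
              class = "cv_score")
  }
  r <- rank_definitions(list(mk("a", 0.3, 5), mk("b", 0.2, 5),
                             mk("c", 0.4, 5)))
  expect_equal(r$definition, c("b", "a", "c"))
  # exact tie, equal parameters: registry order wins
  r2 <- rank_definitions(list(mk("a", 0.2, 5), mk("b", 0.2, 5)))
  expect_equal(r2$definition[1], "a")
  # tie broken by fewer parameters
  r3 <- rank_definitions(list(mk("a", 0.2, 6), mk("b", 0.2, 5)))
  expect_equal(r3$definition[1], "b")
  r4 <- rank_definitions(list(mk("only", 0.5, 3)))
  expect_equal(r4$definition, "only")
  bad <- mk("z", 0.1, 2)
  bad$outcome <- "hlos"
  expect_error(rank_definitions(list(mk("a", 0.2, 5), bad)), "outcome")
})

test_that("Akaike weights and confidence sets follow the closed forms", {
  # equal AICs: symmetric weights, both in the set
  cs <- akaike_confidence_set(c(m1 = 100, m2 = 100))
  expect_equal(cs$weight, c(0.5, 0.5))
  expect_true(all(cs$in_set))

  # AICs 100 and 102: weights 1/(1+e^-1), e^-1/(1+e^-1)
  cs2 <- akaike_confidence_set(c(m1 = 100, m2 = 102))
  expect_equal(cs2$weight[1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(cs2$weight[2], exp(-1) / (1 + exp(-1)), tolerance = 1e-12)
  expect_true(all(cs2$in_set))  # 0.731 then crossing 0.95 at the second

  # a dominant model is the whole confidence set
  cs3 <- akaike_confidence_set(c(m1 = 100, m2 = 120, m3 = 130))
  expect_equal(cs3$weight[1], 1, tolerance = 1e-4)
  expect_equal(cs3$definition[cs3$in_set], "m1")

  expect_equal(sum(cs3$weight), 1, tolerance = 1e-12)
  expect_warning(akaike_confidence_set(c(a = 10, b = Inf)), "non-finite")
})

test_that("confidence sets grow as AIC differences shrink", {
  wide <- akaike_confidence_set(c(a = 100, b = 110, c = 120, d = 130))
  tight <- akaike_confidence_set(c(a = 100, b = 100.5, c = 101, d = 101.5))
  expect_gt(sum(tight$in_set), sum(wide$in_set))
})

test_that("selection reads only the shaping half and is reproducible", {
  co <- generate_cohort(short_config(400, seed = 91,
                                     target_mortality = 0.08,
                                     beta_mortality = 1,
                                     death_before_discharge_prob = 0))
  tab <- cohort_features(co)
  sp <- split_cohort(tab, seed = 13)
  sh <- cohort_half(tab, sp, "shaping")
  reg <- ioh_registry()[c(1, 11, 24), ]  # small registry for speed
  s1 <- suppressMessages(shape_outcome(sh, "mortality", reg, k = 4, reps = 2, seed = 17))
  s2 <- suppressMessages(shape_outcome(sh, "mortality", reg, k = 4, reps = 2, seed = 17))
  expect_identical(s1$table, s2$table)
  expect_setequal(s1$shaping_ids, sh$patient_id)
  expect_equal(s1$best, s1$table$definition[1])
  expect_true(s1$best %in% s1$confidence_set)
  # the confidence set contains the max-weight model
  expect_equal(s1$table$definition[which.max(s1$table$weight)],
               s1$table$definition[s1$table$in_confidence_set][
                 which.max(s1$table$weight[s1$table$in_confidence_set])])
})
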