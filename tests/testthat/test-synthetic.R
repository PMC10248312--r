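test_that("same seed gives identical cohorts, sheets and rater pairs", {
  p <- simulation_params(n_subjects = 300, seed = 99)
  c1 <- generate_cohort(p, default_spec)
  c2 <- generate_cohort(p, default_spec)
  expect_identical(c1, c2)
  s1 <- generate_item_sheets(c1, default_spec, p)
  s2 <- generate_item_sheets(c2, default_spec, p)
  expect_identical(s1, s2)
  expect_identical(generate_rater_pair(s1, default_spec, p),
                   generate_rater_pair(s2, default_spec, p))
  # different seed differs
  c3 <- generate_cohort(simulation_params(n_subjects = 300, seed = 100),
                        default_spec)
  expect_false(identical(c1$total, c3$total))
})

test_that("male score distribution hits the configured moments", {
  p <- simulation_params(n_subjects = 50000, prop_male = 1, seed = 5)
  co <- generate_cohort(p, default_spec)
  expect_lt(abs(mean(co$total) - (-4.81)), 0.3)
  expect_lt(abs(stats::sd(co$total) - 19.1), 0.5)
})

test_that("scores respect instrument-range truncation and bin consistency", {
  co <- small_cohort(n = 3000, seed = 2)
  expect_true(all(co$total >= -34 & co$total <= 46))
  expect_identical(co$bin, assign_bin(co$total, default_spec))
  # event flags imply observed times within follow-up
  for (oc in c("violent", "general")) {
    ev <- co[[paste0(oc, "_event")]] == 1L
    tm <- co[[paste0(oc, "_time")]]
    expect_true(all(!is.na(tm[ev])))
    expect_true(all(tm[ev] <= co$follow_up_years[ev]))
  }
})

test_that("a null slope produces score-independent recidivism", {
  p <- simulation_params(
    n_subjects = 4000, seed = 31,
    outcome_models = list(violent = list(`5` = c(b0 = -2.5, b1 = 0))))
  co <- generate_cohort(p, default_spec)
  fw <- fixed_window_outcomes(co, "violent", 5)
  fit <- fit_logistic(co$total[fw$eligible], fw$event[fw$eligible])
  expect_true(fit$b1 - 1.96 * fit$se_b1 < 0 &&
              fit$b1 + 1.96 * fit$se_b1 > 0)
})

test_that("inconsistent outcome configs fail fast", {
  expect_error(simulation_params(outcome_models = list(violent = list())),
               "no horizon models")
  expect_error(
    simulation_params(outcome_models = list(
      violent = list(`-5` = c(b0 = -2, b1 = 0.04)))),
    "positive")
  expect_error(
    simulation_params(outcome_models = list(
      violent = list(`5` = c(b0 = -2)))),
    "b0/b1")
})

test_that("item sheets preserve totals and respect the missingness cap", {
  co <- small_cohort(n = 250, seed = 3)
  p0 <- simulation_params(n_subjects = 250, seed = 3, missing_item_rate = 0)
  sh0 <- generate_item_sheets(co, default_spec, p0)
  ts0 <- total_score(sh0, default_spec)
  expect_identical(ts0$n_missing, rep(0L, 250))
  expect_identical(ts0$total, co$total)

  p1 <- simulation_params(n_subjects = 250, seed = 3, missing_item_rate = 1)
  sh1 <- generate_item_sheets(co, default_spec, p1)
  expect_identical(total_score(sh1, default_spec)$n_missing, rep(4L, 250))
})

test_that("empirical per-item missingness matches the configured rate", {
  n <- 4000
  co <- small_cohort(n = n, seed = 4)
  p <- simulation_params(n_subjects = n, seed = 4, missing_item_rate = 0.05)
  sh <- generate_item_sheets(co, default_spec, p)
  # the per-sheet cap (4 of 12 at rate .05) almost never binds at this rate
  rates <- colMeans(is.na(sh[default_spec$item_names]))
  se <- sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(rates - 0.05) < 3 * se + 1e-3))
})

test_that("zero rater disagreement gives perfect agreement coefficients", {
  co <- small_cohort(n = 60, seed = 6)
  p <- simulation_params(n_subjects = 60, seed = 6, missing_item_rate = 0,
                         rater_disagreement = 0)
  sh <- generate_item_sheets(co, default_spec, p)
  r2 <- generate_rater_pair(sh, default_spec, p)
  expect_identical(sh, r2)
  b <- assign_bin(total_score(sh, default_spec)$total, default_spec)
  rep_ <- reliability_report(b, b, co$total, co$total)
  expect_equal(rep_$kappa_unweighted, 1)
  expect_equal(rep_$kappa_weighted, 1)
  expect_equal(rep_$ac1$coefficient, 1)
  expect_equal(rep_$ac2$coefficient, 1)
  expect_equal(rep_$icc_oneway$icc, 1)
})

test_that("full uniform re-draw drives weighted kappa toward zero", {
  co <- small_cohort(n = 2500, seed = 7)
  p <- simulation_params(n_subjects = 2500, seed = 7, missing_item_rate = 0,
                         rater_disagreement = 1, rater_magnitude = 13)
  sh <- generate_item_sheets(co, default_spec, p)
  r2 <- generate_rater_pair(sh, default_spec, p)
  b1 <- assign_bin(total_score(sh, default_spec)$total, default_spec)
  b2 <- assign_bin(total_score(r2, default_spec)$total, default_spec)
  k <- cohen_kappa(b1, b2, "quadratic", categories = 1:9)
  expect_lt(abs(as.numeric(k)), 0.06)
})

test_that("small perturbations put weighted agreement above binary", {
  co <- small_cohort(n = 400, seed = 8)
  p <- simulation_params(n_subjects = 400, seed = 8, missing_item_rate = 0,
                         rater_disagreement = 0.2, rater_magnitude = 1)
  sh <- generate_item_sheets(co, default_spec, p)
  r2 <- generate_rater_pair(sh, default_spec, p)
  b1 <- assign_bin(total_score(sh, default_spec)$total, default_spec)
  b2 <- assign_bin(total_score(r2, default_spec)$total, default_spec)
  pb <- percent_agreement(b1, b2, "binary")
  pw <- percent_agreement(b1, b2, "ordinal", categories = 1:9)
  expect_gt(pw, pb)
  # adjacent-bin disagreements dominate
  d <- abs(b1 - b2)
  expect_gt(sum(d == 1), sum(d > 1))
})

test_that("calibration-module regression recovers the generator coefficients", {
  p <- simulation_params(n_subjects = 6000, seed = 12)
  co <- generate_cohort(p, default_spec)
  fw <- fixed_window_outcomes(co, "violent", 5)
  fit <- fit_logistic(co$total[fw$eligible], fw$event[fw$eligible])
  expect_lt(abs(fit$b0 - (-2.856)), 3 * fit$se_b0)
  expect_lt(abs(fit$b1 - 0.040), 3 * fit$se_b1)
})

test_that("a cohort generated under the norms' own rates self-calibrates", {
  # implied per-bin 5-year rates from one large reference draw become the
  # norms; replicate cohorts from the same law should have total E/O CIs
  # covering 1.0 in the bulk of replicates
  p_big <- simulation_params(n_subjects = 20000, seed = 600,
                             follow_up_mixture = data.frame(
                               weight = 1, lo = 10, hi = 20))
  big <- generate_cohort(p_big, default_spec)
  fw <- fixed_window_outcomes(big, "violent", 5)
  rate_b <- vapply(1:9, function(b) {
    i <- fw$eligible & big$bin == b
    sum(fw$event[i]) / sum(i)
  }, numeric(1))
  norms <- norms_table(1:9, rate_b, horizon = 5, source = "self")
  covered <- 0L
  reps <- 25L
  for (r in seq_len(reps)) {
    co <- generate_cohort(
      simulation_params(n_subjects = 1500, seed = 600 + r,
                        follow_up_mixture = data.frame(
                          weight = 1, lo = 10, hi = 20)),
      default_spec)
    eo <- calibration_report(co, norms, "violent")
    tot <- eo[eo$bin == "total", ]
    if (!is.na(tot$eo) && tot$ci_lo <= 1 && tot$ci_hi >= 1) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered, round(0.8 * reps))
})

test_that("diagnosis prevalences and targeted comorbidity are honoured", {
  co <- small_cohort(n = 20000, seed = 13)
  prev <- c(psychotic = 0.845, sud = 0.562, mood = 0.387, aspd = 0.245)
  for (d in names(prev)) {
    emp <- mean(co[[paste0("dx_", d)]])
    # rejection tilt shifts margins slightly; wide but honest bracket
    expect_lt(abs(emp - prev[[d]]), 0.04)
  }
  # antisocial x substance-use co-occurrence is elevated
  p_sud_aspd <- mean(co$dx_sud[co$dx_aspd == 1])
  p_sud <- mean(co$dx_sud)
  expect_gt(p_sud_aspd, p_sud + 0.05)
})

test_that("cohort round-trips through delimited text", {
  co <- small_cohort(n = 50, seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2$total, co$total)
  expect_equal(co2$violent_event, co$violent_event)
  expect_equal(co2$follow_up_years, co$follow_up_years, tolerance = 1e-6)
})
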