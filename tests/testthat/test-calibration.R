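test_that("intercept-only fit equals the closed-form logit of the base rate", {
  y <- c(rep(1L, 22), rep(0L, 361))  # 22 events in 383 trials
  fit <- fit_logistic(rep(0, 383), y)
  expect_equal(fit$b0, log(22 / 361))
  expect_true(is.na(fit$b1))
  expect_identical(fit$n_events, 22L)
})

test_that("IRLS matches glm and an independent grid-search maximizer", {
  set.seed(30)
  for (rep in 1:5) {
    x <- sample(-30:30, 50, replace = TRUE)
    y <- rbinom(50, 1, plogis(-1 + 0.05 * x))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(x, y)
    g <- stats::glm(y ~ x, family = stats::binomial())
    expect_equal(fit$b0, unname(stats::coef(g)[1]), tolerance = 1e-6)
    expect_equal(fit$b1, unname(stats::coef(g)[2]), tolerance = 1e-6)
    expect_equal(fit$se_b0, unname(sqrt(diag(stats::vcov(g)))[1]),
                 tolerance = 1e-4)
    expect_equal(fit$se_b1, unname(sqrt(diag(stats::vcov(g)))[2]),
                 tolerance = 1e-4)
    gr <- grid_logistic(x, y)
    expect_lt(abs(fit$b0 - gr[["b0"]]), 1e-4)
    expect_lt(abs(fit$b1 - gr[["b1"]]), 1e-4)
  }
})

test_that("null-generator slope is covered by the fitted CI", {
  set.seed(31)
  x <- rnorm(2000, 0, 19)
  y <- rbinom(2000, 1, 0.08)  # independent of score
  fit <- fit_logistic(x, y)
  expect_true(fit$b1 - 1.96 * fit$se_b1 < 0 &&
              fit$b1 + 1.96 * fit$se_b1 > 0)
})

test_that("complete separation is reported as such", {
  x <- c(seq(-10, -1), seq(1, 10))
  y <- as.integer(x > 0)
  expect_error(fit_logistic(x, y), "separation")
})

test_that("invariants of logistic_fit", {
  set.seed(32)
  x <- sample(-34:46, 400, replace = TRUE)
  y <- rbinom(400, 1, plogis(-2.856 + 0.04 * x))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  fit <- fit_logistic(x, y)
  expect_equal(fit$odds_ratio, exp(fit$b1))
  expect_gte(fit$wald, 0)
  expect_true(fit$converged)
})

test_that("predict_rate is the exact logistic transform", {
  null_fit <- list(b0 = 0, b1 = 0)
  expect_equal(predict_rate(null_fit, c(-100, 0, 100)), rep(0.5, 3))
  printed <- list(b0 = -2.856, b1 = 0.040)
  expect_equal(predict_rate(printed, 0), exp(-2.856) / (1 + exp(-2.856)))
  expect_equal(predict_rate(printed, 0), 0.0544, tolerance = 1e-3)
  rates <- predict_rate(printed, -34:46)
  expect_true(all(diff(rates) > 0))
  expect_true(all(rates > 0 & rates < 1))
})

test_that("recidivism_curve tabulates the full or restricted range", {
  fit <- list(b0 = -2.856, b1 = 0.040)
  curve <- recidivism_curve(fit, c(-34L, 46L))
  expect_identical(nrow(curve), 81L)
  expect_equal(curve$rate, predict_rate(fit, curve$score))
  sub <- recidivism_curve(fit, c(-10L, 10L))  # subgroup-populated range
  expect_identical(range(sub$score), c(-10L, 10L))
})

test_that("Hosmer-Lemeshow statistic is zero when observed equals expected", {
  p <- rep(seq(0.1, 0.5, by = 0.1), each = 10)
  y <- unlist(lapply(seq(0.1, 0.5, by = 0.1), function(pr) {
    c(rep(1L, round(10 * pr)), rep(0L, 10 - round(10 * pr)))
  }))
  hl <- hosmer_lemeshow(p, y, n_groups = 5)
  expect_equal(hl$statistic, 0)
  expect_identical(hl$df, nrow(hl$groups) - 2L)
})

test_that("Hosmer-Lemeshow is permutation invariant and rejects degenerate input", {
  set.seed(33)
  p <- runif(200, 0.02, 0.4)
  y <- rbinom(200, 1, p)
  h1 <- hosmer_lemeshow(p, y)
  perm <- sample.int(200)
  h2 <- hosmer_lemeshow(p[perm], y[perm])
  expect_equal(h1$statistic, h2$statistic)
  expect_error(hosmer_lemeshow(rep(0.1, 50), rbinom(50, 1, 0.1)),
               "degenerate")
})

test_that("ties in fitted probabilities stay in one group and df adjusts", {
  p <- rep(c(0.1, 0.2, 0.3), times = c(50, 30, 20))
  set.seed(34)
  y <- rbinom(100, 1, p)
  hl <- hosmer_lemeshow(p, y, n_groups = 10)
  expect_lte(nrow(hl$groups), 3L)
  expect_identical(hl$df, nrow(hl$groups) - 2L)
})

test_that("expected counts are rate times n, unrounded", {
  norms <- norms_table(1:9, c(.08, .09, .18, .19, .25, .37, .45, .58, .80),
                       horizon = 5)
  sizes <- stats::setNames(c(87, 64, 53, 48, 32, 43, 21, 30, 27), 1:9)
  E <- expected_counts(norms, sizes)
  expect_equal(unname(E[9]), 21.6)
  expect_equal(unname(E[6]), 15.91)
  expect_equal(round(unname(E[6]), 1), 15.9)  # display rounding
  zero <- norms_table(1, 0, horizon = 5)
  expect_equal(unname(expected_counts(zero, c(`1` = 1000))), 0)
  expect_error(expected_counts(norms_table(1:8, rep(.1, 8), 5),
                               sizes), "no rate for bin")
})

test_that("E/O index and multiplicative CI reproduce printed arithmetic", {
  r <- eo_index(21.6, 5)
  expect_equal(r$eo, 4.32)
  expect_equal(round(r$eo, 1), 4.3)
  # CI half-width multiplier at O = 22
  expect_equal(exp(1.96 * sqrt(1 / 22)), 1.5187, tolerance = 1e-4)
  # perfect calibration is never significant
  p <- eo_index(7, 7)
  expect_equal(p$eo, 1)
  expect_false(p$significant)
  # O = 0: undefined, flagged, E retained
  z <- eo_index(3.2, 0)
  expect_true(is.na(z$eo))
  expect_false(z$significant)
  expect_equal(z$E, 3.2)
})

test_that("E/O properties: scale equivariance, CI width, containment", {
  base <- eo_index(20, 10)
  scaled <- eo_index(3 * 20, 3 * 10)
  expect_equal(scaled$eo, base$eo)
  widths <- vapply(c(5, 20, 80), function(o) {
    r <- eo_index(2 * o, o)
    log(r$ci_hi) - log(r$ci_lo)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  r <- eo_index(13.7, 4)
  expect_true(r$ci_lo < r$eo && r$eo < r$ci_hi)
})

test_that("eo_table reproduces the published overall calibration table", {
  norms <- read_norms(
    system.file("extdata", "norms_5yr_violence.csv", package = "riskcalib"),
    horizon = 5)
  ref <- utils::read.csv(
    system.file("extdata", "reference_eo_counts.csv", package = "riskcalib"))
  tab <- eo_table(stats::setNames(ref$n_overall, ref$bin), ref$O_overall,
                  norms, expected = ref$E_overall)
  tot <- tab[tab$bin == "total", ]
  expect_equal(tot$E, 101.4)
  expect_equal(tot$O, 22)
  expect_equal(round(tot$eo, 1), 4.6)
  expect_equal(round(tot$ci_lo, 2), 3.03, tolerance = 0.01)
  expect_true(tot$significant)
  # per-bin published values
  expect_equal(round(tab$eo[tab$bin == "2"], 1), 2.9)
  expect_equal(round(tab$eo[tab$bin == "9"], 1), 4.3)
  expect_equal(round(tab$eo[tab$bin == "8"], 1), 5.8)
  # without the supplied column, bin 4 E reverts to rate*n
  tab2 <- eo_table(stats::setNames(ref$n_overall, ref$bin), ref$O_overall,
                   norms)
  expect_equal(tab2$E[tab2$bin == "4"], 0.19 * 48)
})

test_that("zero-observed bins are flagged but included in totals", {
  norms <- norms_table(1:3, c(0.1, 0.2, 0.3), horizon = 5)
  tab <- eo_table(c(`1` = 50, `2` = 40, `3` = 30), c(4, 0, 10), norms)
  r2 <- tab[tab$bin == "2", ]
  expect_true(is.na(r2$eo))
  expect_false(r2$significant)
  tot <- tab[tab$bin == "total", ]
  expect_equal(tot$E, 5 + 8 + 9)
  expect_equal(tot$O, 14)
})

test_that("calibration_report is consistent with fixed-window counts", {
  co <- small_cohort(n = 2500, seed = 41)
  norms <- read_norms(
    system.file("extdata", "norms_5yr_violence.csv", package = "riskcalib"),
    horizon = 5)
  eo <- calibration_report(co, norms, "violent")
  fw <- fixed_window_outcomes(co, "violent", 5)
  tot <- eo[eo$bin == "total", ]
  expect_equal(tot$O, fw$n_events)
  expect_equal(tot$n, fw$n_eligible)
  expect_equal(tot$E, sum(eo$E[eo$bin != "total"]))
  # published direction: default synthetic cohort is overpredicted by norms
  expect_gt(tot$eo, 1)
})
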