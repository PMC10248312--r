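#' Logistic score-to-rate model
#'
#' Maximum-likelihood univariate logistic regression of a binary recidivism
#' outcome on a risk score, fit in-package by iteratively reweighted least
#' squares. Standard errors come from the observed information at the
#' optimum; the Wald statistic is `(b1/se_b1)^2` with a 1-df chi-square
#' p-value, and the odds ratio `exp(b1)` carries a Wald 95% CI, matching the
#' B / SE / Wald / e^B layout conventional in validation reports.
#'
#' Convergence: relative log-likelihood change below 1e-10, at most 100
#' iterations. Complete separation (the MLE diverging) is detected and
#' reported as an error; non-convergence errors carry the iteration trace.
#'
#' @param scores numeric predictor.
#' @param outcomes binary 0/1 response.
#' @return object of class `logistic_fit`: `b0`, `b1`, `se_b0`, `se_b1`,
#'   `wald`, `p_value`, `odds_ratio`, `or_ci95`, `converged`, `loglik`,
#'   `n`, `n_events`, `iterations`.
#' @export
fit_logistic <- function(scores, outcomes) {
  keep <- !is.na(scores) & !is.na(outcomes)
  x <- as.numeric(scores[keep])
  y <- as.integer(outcomes[keep])
  if (!all(y %in% 0:1)) stop("outcomes must be binary 0/1")
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")

  if (length(unique(x)) == 1L) {
    # constant score: intercept-only model, closed form
    p_bar <- mean(y)
    b0 <- stats::qlogis(p_bar)           # log(events / non-events)
    se0 <- sqrt(1 / (n * p_bar * (1 - p_bar)))
    return(structure(
      list(b0 = b0, b1 = NA_real_, se_b0 = se0, se_b1 = NA_real_,
           wald = NA_real_, p_value = NA_real_, odds_ratio = NA_real_,
           or_ci95 = c(NA_real_, NA_real_), converged = TRUE,
           loglik = sum(y) * log(p_bar) + sum(1 - y) * log(1 - p_bar),
           n = n, n_events = sum(y), iterations = 0L),
      class = "logistic_fit"))
  }

  X <- cbind(1, x)
  beta <- c(stats::qlogis(mean(y)), 0)
  ll <- function(b) {
    eta <- X %*% b
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(100L)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    if (all(w < 1e-12)) break
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, crossprod(X, y - p)),
                     error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + as.vector(step)
    ll_new <- ll(beta)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll_old) < 1e-10 * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  p_hat <- stats::plogis(as.vector(X %*% beta))
  if (max(abs(beta)) > 30 || all(p_hat[y == 1] > 1 - 1e-8) ||
      all(p_hat[y == 0] < 1e-8)) {
    stop("complete separation: maximum-likelihood estimate does not exist")
  }
  if (!converged) {
    stop("logistic fit did not converge in 100 iterations; log-likelihood ",
         "trace: ", paste(sprintf("%.6f", utils::tail(trace, 5)),
                          collapse = " -> "))
  }
  w <- p_hat * (1 - p_hat)
  info <- crossprod(X, X * w)     # observed = expected information here
  vcov <- solve(info)
  se <- unname(sqrt(diag(vcov)))
  beta <- unname(beta)
  wald <- (beta[2] / se[2])^2
  structure(
    list(b0 = beta[1], b1 = beta[2], se_b0 = se[1], se_b1 = se[2],
         wald = wald,
         p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
         odds_ratio = exp(beta[2]),
         or_ci95 = exp(beta[2] + c(-1.96, 1.96) * se[2]),
         converged = converged, loglik = ll_old,
         n = n, n_events = sum(y), iterations = it),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic fit: B0 = %.3f (SE %.3f), B1 = %.3f (SE %.3f)\n",
    x$b0, x$se_b0, x$b1, x$se_b1))
  cat(sprintf("  Wald = %.3f, p = %.4g, e^B1 = %.3f [%.3f, %.3f]\n",
              x$wald, x$p_value, x$odds_ratio, x$or_ci95[1], x$or_ci95[2]))
  cat(sprintf("  n = %d (%d events), loglik %.3f, %d iterations\n",
              x$n, x$n_events, x$loglik, x$iterations))
  invisible(x)
}

#' Predicted recidivism rate for a score
#'
#' The logistic transform `exp(b0 + b1*score) / (1 + exp(b0 + b1*score))`,
#' evaluated exactly.
#'
#' @param fit a [fit_logistic()] result, or any list with `b0`/`b1`.
#' @param score numeric vector.
#' @export
predict_rate <- function(fit, score) {
  stats::plogis(fit$b0 + fit$b1 * score)
}

#' Score-to-rate curve
#'
#' Tabulates the fitted recidivism rate over an integer score range, for
#' juxtaposition with per-bin observed rates. Subgroup curves conventionally
#' restrict to the scores actually populated within the subgroup; pass that
#' range via `score_range`.
#'
#' @inheritParams predict_rate
#' @param score_range length-2 integer range (inclusive).
#' @return data.frame with `score` and `rate`.
#' @export
recidivism_curve <- function(fit, score_range = c(-34L, 46L)) {
  s <- seq(score_range[1], score_range[2])
  data.frame(score = s, rate = predict_rate(fit, s))
}

#' Hosmer-Lemeshow goodness of fit
#'
#' Subjects are grouped into risk deciles (by default) of fitted
#' probability; subjects with identical fitted probabilities always share a
#' group, so the group count can collapse below `n_groups`. The statistic is
#' `sum((O - E)^2 / (E * (1 - E/n)))` over groups, referred to chi-square
#' with `groups - 2` degrees of freedom.
#'
#' @param fitted_probs fitted event probabilities.
#' @param outcomes binary 0/1.
#' @param n_groups target number of groups (default 10).
#' @return object of class `hl_result`: `statistic`, `df`, `p_value`, and
#'   the per-group table.
#' @export
hosmer_lemeshow <- function(fitted_probs, outcomes, n_groups = 10L) {
  stopifnot(length(fitted_probs) == length(outcomes), n_groups >= 2L)
  y <- as.integer(outcomes)
  p <- as.numeric(fitted_probs)
  if (length(unique(p)) < 2L) {
    stop("degenerate grouping: all fitted probabilities identical")
  }
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_groups + 1),
                               type = 2, names = FALSE))
  if (length(br) < 3L) stop("degenerate grouping: deciles collapse to <2 groups")
  g <- cut(p, breaks = br, include.lowest = TRUE)
  tab <- data.frame(
    group = levels(g),
    n = as.vector(table(g)),
    observed = as.vector(tapply(y, g, sum)),
    expected = as.vector(tapply(p, g, sum))
  )
  tab <- tab[tab$n > 0L, , drop = FALSE]
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- nrow(tab) - 2L
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         groups = tab),
    class = "hl_result"
  )
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Norms table: per-bin expected recidivism rates
#'
#' The reference sample's expected event proportion for each risk bin at a
#' given follow-up horizon. An optional `expected` column lets a published
#' expected-count column be reproduced verbatim when it differs from
#' `rate * n` (validation reports occasionally print inconsistent rows).
#'
#' @param bin integer bin numbers (one rate per bin).
#' @param rate expected event proportions in \[0, 1\].
#' @param horizon follow-up years the rates refer to.
#' @param source free-text provenance tag.
#' @param label optional bin range labels.
#' @return data.frame of class `norms_table`.
#' @export
norms_table <- function(bin, rate, horizon, source = "unspecified",
                        label = NULL) {
  stopifnot(length(bin) == length(rate), !anyDuplicated(bin),
            all(rate >= 0 & rate <= 1), horizon > 0)
  out <- data.frame(bin = as.integer(bin), rate = as.numeric(rate))
  out$label <- if (is.null(label)) as.character(bin) else label
  attr(out, "horizon") <- horizon
  attr(out, "source") <- source
  class(out) <- c("norms_table", "data.frame")
  out
}

#' Read a norms table from delimited text
#'
#' Expects columns `bin` and `rate` (proportion or percent; percents are
#' detected when any value exceeds 1 and divided by 100), optional `label`.
#'
#' @param path CSV path.
#' @inheritParams norms_table
#' @export
read_norms <- function(path, horizon, source = basename(path)) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("bin", "rate") %in% names(x))) {
    stop("norms file needs 'bin' and 'rate' columns")
  }
  r <- x$rate
  if (any(r > 1)) r <- r / 100
  norms_table(x$bin, r, horizon, source,
              label = if ("label" %in% names(x)) x$label else NULL)
}

#' Expected event counts per bin
#'
#' `E_b = rate_b * n_b`, kept unrounded internally (display rounding is the
#' caller's concern so totals do not compound rounding error).
#'
#' @param norms a [norms_table()].
#' @param bin_sizes named or bin-ordered integer vector of per-bin n; names
#'   (or positions) are bin numbers.
#' @return numeric vector of expected counts, named by bin.
#' @export
expected_counts <- function(norms, bin_sizes) {
  stopifnot(inherits(norms, "norms_table"))
  bins <- if (!is.null(names(bin_sizes))) as.integer(names(bin_sizes))
          else seq_along(bin_sizes)
  missing_bins <- setdiff(bins[bin_sizes > 0], norms$bin)
  if (length(missing_bins)) {
    stop("norms table has no rate for bin(s): ",
         paste(missing_bins, collapse = ", "))
  }
  rate <- norms$rate[match(bins, norms$bin)]
  stats::setNames(rate * as.numeric(bin_sizes), bins)
}

#' Expected/observed (E/O) index with multiplicative 95% CI
#'
#' `E/O > 1` means the reference norms over-predict recidivism in the
#' validation cohort. The 95% CI is multiplicative,
#' `(E/O) * exp(+/- 1.96 * sqrt(1/O))` (Rockhill's formulation), and the
#' index is flagged significant when the CI excludes 1. With `O = 0` the
#' index is undefined and returned as a flagged `NA` row with the expected
#' count only.
#'
#' @param E expected event count(s), > 0.
#' @param O observed event count(s), same length.
#' @return data.frame with `E`, `O`, `eo`, `ci_lo`, `ci_hi`, `significant`.
#' @export
eo_index <- function(E, O) {
  stopifnot(length(E) == length(O), all(E > 0), all(O >= 0))
  eo <- ifelse(O > 0, E / O, NA_real_)
  half <- exp(1.96 * sqrt(1 / ifelse(O > 0, O, NA_real_)))
  lo <- eo / half
  hi <- eo * half
  data.frame(E = E, O = O, eo = eo, ci_lo = lo, ci_hi = hi,
             significant = !is.na(eo) & (lo > 1 | hi < 1))
}

#' E/O table from per-bin counts
#'
#' Builds the per-bin plus total expected/observed comparison from raw
#' counts, without needing subject-level data: per-bin `E` is
#' `rate_b * n_b` from the norms unless a published `expected` column is
#' supplied, the total row sums per-bin `E` and `O`, and each row carries
#' the E/O index with its multiplicative CI. Zero-observed bins are flagged
#' (no CI) but still contribute to the totals.
#'
#' @param bin_sizes per-bin subject counts (bin-ordered or named by bin).
#' @param observed per-bin observed event counts, aligned with `bin_sizes`.
#' @param norms a [norms_table()].
#' @param expected optional per-bin expected counts overriding `rate * n`
#'   (e.g. a published expected-count column).
#' @return data.frame of class `eo_table`: per-bin rows plus a `"total"`
#'   row, columns `bin`, `n`, `expected_rate`, `E`, `O`, `observed_rate`,
#'   `eo`, `ci_lo`, `ci_hi`, `significant`.
#' @export
eo_table <- function(bin_sizes, observed, norms, expected = NULL) {
  stopifnot(length(bin_sizes) == length(observed),
            all(observed <= bin_sizes))
  E <- expected_counts(norms, bin_sizes)
  if (!is.null(expected)) {
    stopifnot(length(expected) == length(bin_sizes))
    E <- stats::setNames(as.numeric(expected), names(E))
  }
  bins <- as.integer(names(E))
  n <- as.numeric(bin_sizes)
  O <- as.numeric(observed)
  rows <- eo_index(E, O)
  tot <- eo_index(sum(E), sum(O))
  out <- data.frame(
    bin = c(as.character(bins), "total"),
    n = c(n, sum(n)),
    expected_rate = c(E / n, sum(E) / sum(n)),
    E = c(E, sum(E)),
    O = c(O, sum(O)),
    observed_rate = c(O / n, sum(O) / sum(n)),
    eo = c(rows$eo, tot$eo),
    ci_lo = c(rows$ci_lo, tot$ci_lo),
    ci_hi = c(rows$ci_hi, tot$ci_hi),
    significant = c(rows$significant, tot$significant),
    stringsAsFactors = FALSE
  )
  class(out) <- c("eo_table", "data.frame")
  out
}

#' Calibration report against a norms table
#'
#' Bins the cohort, constructs the fixed-window outcome at the norms'
#' horizon, and compares per-bin observed recidivist counts with the counts
#' the norms expect via [eo_table()]. Only bins populated in the cohort are
#' tabulated.
#'
#' @param cohort a `cohort` data.frame.
#' @param norms a [norms_table()]; its `horizon` attribute sets the window.
#' @param outcome outcome prefix, e.g. `"violent"`.
#' @param expected optional published per-bin expected counts (aligned with
#'   the populated bins, ascending).
#' @return an `eo_table`.
#' @export
calibration_report <- function(cohort, norms, outcome = "violent",
                               expected = NULL) {
  stopifnot(inherits(norms, "norms_table"))
  horizon <- attr(norms, "horizon")
  fw <- fixed_window_outcomes(cohort, outcome, horizon)
  el <- fw$eligible
  bins_present <- sort(unique(cohort$bin[el]))
  n_b <- stats::setNames(
    vapply(bins_present, function(b) sum(cohort$bin[el] == b), numeric(1)),
    bins_present)
  o_b <- vapply(bins_present, function(b) {
    sum(fw$event[el & cohort$bin == b])
  }, numeric(1))
  eo_table(n_b, o_b, norms, expected = expected)
}
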