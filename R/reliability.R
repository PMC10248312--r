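# Interrater and internal-consistency battery: ICC variants, Cohen's kappa
# (unweighted/weighted), Gwet's AC1/AC2, percent agreement, Cronbach's
# alpha.  All coefficients are authored here (no external agreement
# package in the runtime), each validated against closed-form hand
# computations and, where available, established oracles in the test
# suite.

agreement_weights <- function(q, scheme = c("identity", "linear",
                                            "quadratic")) {
  scheme <- match.arg(scheme)
  k <- matrix(seq_len(q), q, q)
  d <- abs(k - t(k))
  switch(scheme,
         identity = (d == 0) * 1,
         linear = 1 - d / (q - 1),
         quadratic = 1 - (d / (q - 1))^2)
}

rating_table <- function(r1, r2, categories = NULL) {
  stopifnot(length(r1) == length(r2), length(r1) >= 1L)
  if (is.null(categories)) categories <- sort(unique(c(r1, r2)))
  f1 <- factor(r1, levels = categories)
  f2 <- factor(r2, levels = categories)
  if (anyNA(f1) || anyNA(f2)) stop("ratings outside the category set")
  table(f1, f2)
}

#' Single-measure intraclass correlation
#'
#' Variance-component ICC for a subjects x raters matrix via the matching
#' ANOVA decomposition:
#' * `oneway`: one-way random effects (raters nested in subjects), the
#'   model conventional for interrater reliability of totals when raters
#'   are not crossed consistently; absolute-agreement by construction.
#' * `twoway_consistency`: two-way, rater effects removed (shift-invariant).
#' * `twoway_agreement`: two-way absolute agreement, rater variance counted.
#'
#' CIs: exact F bounds for `oneway` and `twoway_consistency`; Satterthwaite
#' approximation (McGraw & Wong) for `twoway_agreement`.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (>= 5 subjects, >= 2 raters).
#' @param model `"oneway"`, `"twoway_consistency"`, or
#'   `"twoway_agreement"`.
#' @param conf confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci95`, `model`, `f`,
#'   `p_value`, `n`, `k`.
#' @export
icc_single <- function(ratings,
                       model = c("oneway", "twoway_consistency",
                                 "twoway_agreement"),
                       conf = 0.95) {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 5L, k >= 2L, !anyNA(x))
  alpha <- 1 - conf
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssb <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((x - grand)^2)
  msb <- ssb / (n - 1)
  msw <- (sst - ssb) / (n * (k - 1))
  mse <- (sst - ssb - ssc) / ((n - 1) * (k - 1))
  msc <- ssc / (k - 1)

  if (msb <= .Machine$double.eps * max(1, abs(grand))) {
    warning("zero between-subject variance; ICC reported as 0")
    return(structure(list(icc = 0, ci95 = c(NA_real_, NA_real_),
                          model = model, f = NA_real_, p_value = NA_real_,
                          n = n, k = k), class = "icc_result"))
  }

  if (model == "oneway") {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    f <- msb / msw
    df1 <- n - 1; df2 <- n * (k - 1)
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  } else if (model == "twoway_consistency") {
    icc <- (msb - mse) / (msb + (k - 1) * mse)
    f <- msb / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  } else {
    icc <- (msb - mse) / (msb + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msb - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msb)
    hi <- n * (f_u * msb - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msb)
    ci <- c(lo, hi)
    f <- msb / mse
    p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc, ci95 = pmin(pmax(ci, -1), 1), model = model,
                 f = f, p_value = p, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single measure) = %.3f, 95%% CI [%.3f, %.3f], p = %.4g\n",
              x$model, x$icc, x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}

#' Cohen's kappa (unweighted or weighted)
#'
#' Chance-corrected agreement under rater-margin independence. For ordered
#' categories, `linear` or `quadratic` distance weights credit near-misses;
#' `quadratic` is the common convention for many-category ordinal scales and
#' the package default where a weighted kappa is requested downstream.
#'
#' @param r1,r2 paired ratings.
#' @param weights `"none"`, `"linear"`, or `"quadratic"`.
#' @param categories category set (ordered); defaults to the sorted union
#'   of observed ratings. Supply the full scale (e.g. `1:9`) when not all
#'   categories are observed.
#' @return kappa, with attributes `weights` and `po`/`pe`; `NA` (with a
#'   warning) when both raters use a single category.
#' @export
cohen_kappa <- function(r1, r2, weights = c("none", "linear", "quadratic"),
                        categories = NULL) {
  weights <- match.arg(weights)
  tab <- rating_table(r1, r2, categories)
  q <- nrow(tab)
  p <- tab / sum(tab)
  w <- agreement_weights(q, if (weights == "none") "identity" else weights)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (abs(1 - pe) < 1e-12) {
    warning("kappa undefined: expected agreement is 1 ",
            "(single category used by both raters)")
    return(structure(NA_real_, weights = weights))
  }
  structure((po - pe) / (1 - pe), weights = weights, po = po, pe = pe)
}

#' Gwet's AC1 / AC2 chance-corrected agreement
#'
#' Gwet's coefficients replace kappa's margin-product chance term with a
#' prevalence-based one, making them robust to skewed category use. AC1 is
#' the unweighted variant; AC2 applies ordinal agreement weights (default
#' quadratic) and requires ordered categories. AC2 with identity weights
#' reduces exactly to AC1.
#'
#' The variance is Gwet's two-rater linearized estimator; the CI uses
#' Student's t with `n - 1` degrees of freedom.
#'
#' @inheritParams cohen_kappa
#' @param variant `"AC1"` or `"AC2"`.
#' @param weights agreement-weight scheme for AC2 (`"quadratic"`,
#'   `"linear"`, or `"identity"`).
#' @param conf confidence level.
#' @return object of class `gwet_result`: `coefficient`, `se`, `ci95`,
#'   `variant`, `weights`, `n`.
#' @export
gwet <- function(r1, r2, variant = c("AC1", "AC2"),
                 weights = c("quadratic", "linear", "identity"),
                 categories = NULL, conf = 0.95) {
  variant <- match.arg(variant)
  weights <- match.arg(weights)
  if (variant == "AC1") weights <- "identity"
  if (is.null(categories)) categories <- sort(unique(c(r1, r2)))
  q <- length(categories)
  if (q < 2L) stop("need at least 2 categories")
  n <- length(r1)
  i1 <- match(r1, categories)
  i2 <- match(r2, categories)
  if (anyNA(i1) || anyNA(i2)) stop("ratings outside the category set")
  w <- agreement_weights(q, weights)
  tw <- sum(w)

  pa_i <- w[cbind(i1, i2)]
  pa <- mean(pa_i)
  pi_k <- (tabulate(i1, q) + tabulate(i2, q)) / (2 * n)
  pe <- tw / (q * (q - 1)) * sum(pi_k * (1 - pi_k))
  if (abs(1 - pe) < 1e-12) stop("chance agreement is 1; coefficient undefined")
  coef <- (pa - pe) / (1 - pe)

  # two-rater linearized variance (Gwet)
  pe_i <- tw / (q * (q - 1)) *
    ((1 - pi_k)[i1] + (1 - pi_k)[i2]) / 2
  gam_i <- (pa_i - pe) / (1 - pe) -
    2 * (1 - coef) * (pe_i - pe) / (1 - pe)
  v <- sum((gam_i - mean(gam_i))^2) / (n * (n - 1))
  se <- sqrt(v)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  ci <- pmin(pmax(coef + c(-1, 1) * tcrit * se, -1), 1)
  structure(list(coefficient = coef, se = se, ci95 = ci, variant = variant,
                 weights = weights, pa = pa, pe = pe, n = n),
            class = "gwet_result")
}

#' @export
print.gwet_result <- function(x, ...) {
  cat(sprintf("Gwet's %s (%s weights) = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$variant, x$weights, x$coefficient, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Percent agreement (binary or ordinal-weighted)
#'
#' Binary: proportion of exact matches. Ordinal: mean per-subject agreement
#' weight under the quadratic kernel on the supplied category set -- the
#' same kernel as weighted AC2, so adjacent-category disagreements on a
#' nine-category scale each cost only `(1/8)^2`.
#'
#' @inheritParams cohen_kappa
#' @param weights `"binary"` or `"ordinal"`.
#' @export
percent_agreement <- function(r1, r2, weights = c("binary", "ordinal"),
                              categories = NULL) {
  weights <- match.arg(weights)
  stopifnot(length(r1) == length(r2))
  if (weights == "binary") return(mean(r1 == r2))
  if (is.null(categories)) categories <- sort(unique(c(r1, r2)))
  q <- length(categories)
  w <- agreement_weights(q, "quadratic")
  i1 <- match(r1, categories); i2 <- match(r2, categories)
  if (anyNA(i1) || anyNA(i2)) stop("ratings outside the category set")
  mean(w[cbind(i1, i2)])
}

#' Cronbach's alpha
#'
#' Internal consistency of an item battery:
#' `(k/(k-1)) * (1 - sum(item variances) / var(total))`.
#'
#' @param items numeric matrix, subjects x items (>= 2 items).
#' @return alpha; `NA` with a warning when the total score has zero
#'   variance.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  stopifnot(ncol(x) >= 2L, !anyNA(x))
  k <- ncol(x)
  vt <- stats::var(rowSums(x))
  if (vt <= .Machine$double.eps) {
    warning("alpha undefined: zero total-score variance")
    return(NA_real_)
  }
  (k / (k - 1)) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

#' Full interrater / internal-consistency report
#'
#' Runs the whole battery on a pair of raters' bin-level ratings plus
#' (optionally) continuous totals and an item matrix, mirroring the
#' conventional reporting block of a validation study: one-way single-
#' measure ICC on totals, unweighted and quadratic-weighted kappa, Gwet's
#' AC1 and quadratic AC2, binary and ordinal percent agreement, and
#' Cronbach's alpha when items are supplied.
#'
#' @param bins1,bins2 paired ordinal bin ratings (categories 1..9 by
#'   default).
#' @param totals1,totals2 optional paired continuous totals (for the ICC).
#' @param items optional subjects x items matrix (for alpha).
#' @param categories ordered category set for the bin-level coefficients.
#' @param kappa_weights weight scheme for the weighted kappa / AC2.
#' @return list of class `reliability_report`.
#' @export
reliability_report <- function(bins1, bins2, totals1 = NULL, totals2 = NULL,
                               items = NULL, categories = 1:9,
                               kappa_weights = "quadratic") {
  out <- list(
    kappa_unweighted = as.numeric(cohen_kappa(bins1, bins2, "none",
                                              categories)),
    kappa_weighted = as.numeric(cohen_kappa(bins1, bins2, kappa_weights,
                                            categories)),
    kappa_weight_scheme = kappa_weights,
    ac1 = gwet(bins1, bins2, "AC1", categories = categories),
    ac2 = gwet(bins1, bins2, "AC2", weights = kappa_weights,
               categories = categories),
    pct_agreement_binary = percent_agreement(bins1, bins2, "binary"),
    pct_agreement_weighted = percent_agreement(bins1, bins2, "ordinal",
                                               categories)
  )
  if (!is.null(totals1) && !is.null(totals2)) {
    m <- cbind(totals1, totals2)
    out$icc_oneway <- icc_single(m, "oneway")
    out$icc_consistency <- icc_single(m, "twoway_consistency")
  }
  if (!is.null(items)) out$alpha <- cronbach_alpha(items)
  class(out) <- "reliability_report"
  out
}

#' @export
print.reliability_report <- function(x, ...) {
  if (!is.null(x$icc_oneway)) print(x$icc_oneway)
  cat(sprintf("kappa unweighted = %.3f, kappa weighted (%s) = %.3f\n",
              x$kappa_unweighted, x$kappa_weight_scheme, x$kappa_weighted))
  print(x$ac1); print(x$ac2)
  cat(sprintf("percent agreement: binary = %.3f, weighted = %.3f\n",
              x$pct_agreement_binary, x$pct_agreement_weighted))
  if (!is.null(x$alpha)) cat(sprintf("Cronbach's alpha = %.3f\n", x$alpha))
  invisible(x)
}
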