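#' Mann-Whitney AUC with Hanley-McNeil confidence interval
#'
#' The area under the ROC curve computed as the probability that a randomly
#' selected recidivist outscores a randomly selected nonrecidivist, with
#' ties counted 1/2 (midranks). The default standard error is Hanley &
#' McNeil's, with a normal-theory 95% interval clipped to \[0, 1\]; a
#' stratified bootstrap interval is available via `ci = "bootstrap"`.
#'
#' @param scores numeric vector.
#' @param outcomes binary vector (1 = event/recidivist), same length.
#' @param ci `"hanley"` (default) or `"bootstrap"`.
#' @param boot_reps bootstrap replicates when `ci = "bootstrap"`.
#' @return object of class `roc_result`: `auc`, `se`, `ci95`,
#'   `n_recidivists`, `n_nonrecidivists`, `effect_label`, `unstable`
#'   (fewer than 5 subjects in either class).
#' @export
roc_auc <- function(scores, outcomes, ci = c("hanley", "bootstrap"),
                    boot_reps = 2000L) {
  ci <- match.arg(ci)
  stopifnot(length(scores) == length(outcomes))
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]
  outcomes <- as.integer(outcomes[keep])
  if (!all(outcomes %in% 0:1)) stop("outcomes must be binary 0/1")
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both outcome classes must be present")
  }
  a <- auc_midrank(scores, outcomes)
  se <- hanley_mcneil_se(a, n1, n0)
  if (ci == "hanley") {
    lo <- max(0, a - 1.96 * se)
    hi <- min(1, a + 1.96 * se)
  } else {
    i1 <- which(outcomes == 1L)
    i0 <- which(outcomes == 0L)
    reps <- vapply(seq_len(boot_reps), function(r) {
      j <- c(sample(i1, n1, replace = TRUE), sample(i0, n0, replace = TRUE))
      auc_midrank(scores[j], outcomes[j])
    }, numeric(1))
    q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    lo <- max(0, q[1]); hi <- min(1, q[2])
  }
  structure(
    list(auc = a, se = se, ci95 = c(lo, hi),
         n_recidivists = n1, n_nonrecidivists = n0,
         effect_label = effect_label(a),
         unstable = min(n1, n0) < 5L),
    class = "roc_result"
  )
}

auc_midrank <- function(scores, outcomes) {
  r <- rank(scores)  # midranks: ties counted 1/2
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

hanley_mcneil_se <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
         (n1 * n0))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f), %d events / %d
non-events, effect: %s%s\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$n_recidivists,
              x$n_nonrecidivists, x$effect_label,
              if (x$unstable) " [unstable: <5 in a class]" else ""))
  invisible(x)
}

#' Effect-size label for an AUC
#'
#' The conventional thresholds for risk-tool AUCs: .556 small, .639 medium,
#' .714 large (Rice & Harris' d-equivalent ladder).
#'
#' @param auc AUC in \[0, 1\].
#' @return one of `"below-small"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_label <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  cut(auc, breaks = c(-Inf, 0.556, 0.639, 0.714, Inf), right = FALSE,
      labels = c("below-small", "small", "medium", "large")) |>
    as.character()
}

#' Discrimination by subgroup
#'
#' AUCs per subgroup for both score representations (continuous total and
#' risk bin), one or more outcomes, and one or more follow-up horizons.
#' Subgroups with only one outcome class present are skipped with a logged
#' reason (attribute `skipped`); subgroups with fewer than 5 subjects in
#' either class are flagged `unstable`.
#'
#' @param cohort a `cohort` data.frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param grouping `"sex"`, a `dx_*` diagnosis column name, or `"none"`.
#' @param outcomes character vector of outcome prefixes (e.g. `"violent"`).
#' @param horizons numeric vector of years; `Inf` = overall follow-up.
#' @return tidy data.frame, one row per subgroup x measure x outcome x
#'   horizon, with AUC, SE, CI bounds, class sizes, effect label, and
#'   stability flag; skipped analyses in `attr(, "skipped")`.
#' @export
subgroup_discrimination <- function(cohort, grouping = "none",
                                    outcomes = c("violent", "general"),
                                    horizons = c(5, 10, Inf)) {
  groups <- if (identical(grouping, "none")) {
    list(all = rep(TRUE, nrow(cohort)))
  } else if (identical(grouping, "sex")) {
    lapply(stats::setNames(nm = unique(cohort$sex)),
           function(s) cohort$sex == s)
  } else {
    if (!grouping %in% names(cohort)) stop("unknown grouping: ", grouping)
    lapply(stats::setNames(nm = c("with", "without")), function(g) {
      if (g == "with") cohort[[grouping]] == 1L else cohort[[grouping]] == 0L
    })
  }
  rows <- list()
  skipped <- character()
  for (g in names(groups)) {
    sub <- cohort[groups[[g]], , drop = FALSE]
    for (oc in outcomes) {
      for (h in horizons) {
        fw <- fixed_window_outcomes(sub, oc, h)
        el <- fw$eligible
        y <- fw$event[el]
        if (nrow(sub) == 0L || length(unique(y)) < 2L) {
          skipped <- c(skipped, sprintf(
            "%s / %s / %s-year: insufficient events in subgroup", g, oc,
            format(h)))
          next
        }
        for (measure in c("total", "bin")) {
          sc <- sub[[if (measure == "total") "total" else "bin"]][el]
          r <- roc_auc(sc, y)
          rows[[length(rows) + 1L]] <- data.frame(
            subgroup = g, measure = measure, outcome = oc,
            horizon = h, auc = r$auc, se = r$se,
            ci_lo = r$ci95[1], ci_hi = r$ci95[2],
            n_recidivists = r$n_recidivists,
            n_nonrecidivists = r$n_nonrecidivists,
            effect = r$effect_label, unstable = r$unstable,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subgroup = character(), measure = character(),
               outcome = character(), horizon = numeric(),
               auc = numeric(), se = numeric(), ci_lo = numeric(),
               ci_hi = numeric(), n_recidivists = integer(),
               n_nonrecidivists = integer(), effect = character(),
               unstable = logical())
  attr(out, "skipped") <- skipped
  out
}
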