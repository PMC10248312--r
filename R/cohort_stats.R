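# Descriptive and comparative cohort statistics: bin frequency tables,
# Welch t with Cohen's d, chi-square with Cramer's V, fixed-window outcome
# construction, and conviction-record recidivism coding.

#' Bin frequency table with per-bin score summaries
#'
#' Per-bin n (with percent), mean and SD of the total score, plus a total
#' row and min/max -- the standard descriptive layout for a binned
#' actuarial instrument, optionally split by sex.
#'
#' @param cohort a `cohort` data.frame with `bin` and `total`.
#' @param by `"none"` or `"sex"`.
#' @param bins bin numbers to tabulate (empty bins are retained with n = 0
#'   and undefined mean).
#' @return data.frame (one block per group when `by = "sex"`), columns
#'   `group`, `bin`, `n`, `pct`, `mean`, `sd`; bin `"total"` rows carry the
#'   group summaries, `"min"`/`"max"` the range.
#' @export
bin_frequency_table <- function(cohort, by = c("none", "sex"), bins = 1:9) {
  by <- match.arg(by)
  groups <- if (by == "none") list(all = rep(TRUE, nrow(cohort)))
            else lapply(stats::setNames(nm = sort(unique(cohort$sex))),
                        function(s) cohort$sex == s)
  blocks <- lapply(names(groups), function(g) {
    sub <- cohort[groups[[g]], , drop = FALSE]
    n_b <- vapply(bins, function(b) sum(sub$bin == b), numeric(1))
    m_b <- vapply(bins, function(b) {
      if (any(sub$bin == b)) mean(sub$total[sub$bin == b]) else NA_real_
    }, numeric(1))
    s_b <- vapply(bins, function(b) {
      if (sum(sub$bin == b) > 1L) stats::sd(sub$total[sub$bin == b])
      else NA_real_
    }, numeric(1))
    rbind(
      data.frame(group = g, bin = as.character(bins), n = n_b,
                 pct = 100 * n_b / max(1, nrow(sub)), mean = m_b, sd = s_b,
                 stringsAsFactors = FALSE),
      data.frame(group = g, bin = "total", n = nrow(sub), pct = 100,
                 mean = mean(sub$total), sd = stats::sd(sub$total),
                 stringsAsFactors = FALSE),
      data.frame(group = g, bin = c("min", "max"), n = NA_real_,
                 pct = NA_real_,
                 mean = if (nrow(sub)) range(sub$total) else c(NA, NA),
                 sd = NA_real_, stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, blocks)
}

#' Welch two-sample t test with Cohen's d
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom,
#' computable from raw vectors or published summaries (mean/SD/n per
#' group). Cohen's d is reported under both the pooled-SD standardiser and
#' the mean-of-SDs standardiser -- published ds are frequently the latter,
#' so both variants are always tagged and returned.
#'
#' @param x,y raw numeric vectors, or `NULL` when using summaries.
#' @param summary1,summary2 optional `c(mean=, sd=, n=)` per group
#'   (override `x`/`y`).
#' @return object of class `ttest_result`: `t`, `df`, `p`, `d_pooled`,
#'   `d_mean_sd`, `mean_diff`.
#' @export
welch_t <- function(x = NULL, y = NULL, summary1 = NULL, summary2 = NULL) {
  if (is.null(summary1)) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    summary1 <- c(mean = mean(x), sd = stats::sd(x), n = length(x))
    summary2 <- c(mean = mean(y), sd = stats::sd(y), n = length(y))
  }
  m1 <- summary1[["mean"]]; s1 <- summary1[["sd"]]; n1 <- summary1[["n"]]
  m2 <- summary2[["mean"]]; s2 <- summary2[["sd"]]; n2 <- summary2[["n"]]
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) stop("zero variance in both groups")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t_stat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  structure(
    list(t = t_stat, df = df, p = p,
         d_pooled = (m1 - m2) / sp,
         d_mean_sd = (m1 - m2) / ((s1 + s2) / 2),
         mean_diff = m1 - m2),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Welch t(%.3f) = %.3f, p = %.4g\n", x$df, x$t, x$p))
  cat(sprintf("Cohen's d: pooled-SD %.3f, mean-SD %.3f\n",
              x$d_pooled, x$d_mean_sd))
  invisible(x)
}

#' Pearson chi-square with Cramer's V
#'
#' Classical contingency-table test of association, without continuity
#' correction; `V = sqrt(chi2 / (n * min(r-1, c-1)))`, which equals phi for
#' a two-level factor.
#'
#' @param tab r x c matrix (or table) of non-negative counts.
#' @return object of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `cramers_v`, `expected`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), sum(tab) > 0)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) stop("zero margin in row ",
                         which(rs == 0)[1])
  if (any(cs == 0)) stop("zero margin in column ",
                         which(cs == 0)[1])
  n <- sum(tab)
  E <- outer(rs, cs) / n
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  v <- sqrt(stat / (n * min(nrow(tab) - 1L, ncol(tab) - 1L)))
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         cramers_v = v, expected = E),
    class = "chisq_result"
  )
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.2f, p = %.4g, Cramer's V = %.3f\n",
              x$df, x$statistic, x$p_value, x$cramers_v))
  invisible(x)
}

#' Fixed-window recidivism outcomes
#'
#' Binary outcome within a fixed follow-up window. A subject is *eligible*
#' for a horizon iff their follow-up covers the window OR they recidivated
#' before the window closed; non-recidivists with shorter follow-up are
#' excluded from the denominator (the rule that reproduces denominators
#' shrinking from the overall to the fixed windows). `horizon = Inf` gives
#' the overall (unfixed) outcome.
#'
#' @param cohort a `cohort` data.frame with `follow_up_years`,
#'   `<outcome>_event`, `<outcome>_time`.
#' @param outcome outcome prefix (e.g. `"violent"`).
#' @param horizon years, or `Inf`.
#' @return list with per-subject `eligible` and `event` vectors plus the
#'   `rate` summary (`events / eligible`).
#' @export
fixed_window_outcomes <- function(cohort, outcome = "violent",
                                  horizon = 5) {
  ev_col <- paste0(outcome, "_event")
  tm_col <- paste0(outcome, "_time")
  if (!all(c(ev_col, tm_col) %in% names(cohort))) {
    stop("cohort lacks columns for outcome '", outcome, "'")
  }
  stopifnot(horizon > 0)
  ev <- cohort[[ev_col]] == 1L
  tm <- cohort[[tm_col]]
  if (any(!is.na(tm) & tm < 0) || any(cohort$follow_up_years < 0)) {
    stop("negative follow-up or event time")
  }
  event_in_window <- ev & !is.na(tm) & tm <= horizon
  eligible <- cohort$follow_up_years >= horizon | event_in_window
  if (is.infinite(horizon)) eligible <- rep(TRUE, nrow(cohort))
  list(
    eligible = eligible,
    event = as.integer(event_in_window),
    n_eligible = sum(eligible),
    n_events = sum(event_in_window[eligible]),
    rate = sum(event_in_window[eligible]) / max(1L, sum(eligible))
  )
}

#' Default violent-offense category list
#'
#' Offense categories counted as violent (offenses against the person with
#' potential for physical or psychological harm, including sexual
#' offenses). Override via the `violent_categories` argument of
#' [recidivism_coding()] or a config file.
#'
#' @export
default_violent_offenses <- function() {
  c("assault", "homicide", "attempted_homicide", "robbery",
    "sexual_assault", "sexual_offense", "kidnapping", "uttering_threats",
    "criminal_harassment", "arson_endangering_life", "weapons_violence")
}

#' Code conviction records into recidivism flags
#'
#' Collapses a long conviction-record table into per-subject binary violent
#' and general recidivism flags with first-event times. Violent convictions
#' are those whose category is in the violent list; every conviction counts
#' toward general recidivism, so violent implies general.
#'
#' @param records data.frame with `subject_id`, `offense_category`, and
#'   `years_to_conviction` (time from discharge).
#' @param violent_categories character vector of violent categories.
#' @param on_unknown `"error"` (default) or `"nonviolent"`: how to treat
#'   categories in neither the violent list nor `known_nonviolent`.
#' @param known_nonviolent categories accepted silently as nonviolent.
#' @return data.frame, one row per subject present in `records`:
#'   `subject_id`, `violent_event`, `violent_time`, `general_event`,
#'   `general_time`.
#' @export
recidivism_coding <- function(records,
                              violent_categories = default_violent_offenses(),
                              on_unknown = c("error", "nonviolent"),
                              known_nonviolent = c(
                                "theft", "fraud", "mischief", "drug_offense",
                                "breach_of_conditions", "property_offense",
                                "impaired_driving")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(all(c("subject_id", "offense_category",
                  "years_to_conviction") %in% names(records)))
  if (any(records$years_to_conviction < 0)) {
    stop("negative time to conviction")
  }
  unknown <- setdiff(records$offense_category,
                     c(violent_categories, known_nonviolent))
  if (length(unknown)) {
    msg <- paste("unknown offense categories:",
                 paste(unknown, collapse = ", "))
    if (on_unknown == "error") stop(msg)
    warning(msg, "; treated as nonviolent")
  }
  records$violent <- records$offense_category %in% violent_categories
  ids <- unique(records$subject_id)
  first_time <- function(id, violent_only) {
    t <- records$years_to_conviction[
      records$subject_id == id & (!violent_only | records$violent)]
    if (length(t)) min(t) else NA_real_
  }
  vt <- vapply(ids, first_time, numeric(1), violent_only = TRUE)
  gt <- vapply(ids, first_time, numeric(1), violent_only = FALSE)
  data.frame(
    subject_id = ids,
    violent_event = as.integer(!is.na(vt)),
    violent_time = vt,
    general_event = as.integer(!is.na(gt)),
    general_time = gt,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
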