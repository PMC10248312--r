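#' Simulation parameters for a synthetic NCRMD-style cohort
#'
#' Defaults emulate the published structure of a provincial
#' not-criminally-responsible (NCRMD) validation cohort: 83.1% male;
#' sex-specific total-score distributions (male mean -4.81, SD 19.1;
#' female mean -16.61, SD 14.9) truncated to the instrument range and
#' rounded to integers; fixed-window recidivism generated from logistic
#' score-to-rate models (5-year violence intercept -2.856 and slope 0.040
#' per score point; 10-year violence -2.471 / 0.041); diagnostic
#' prevalences (psychotic 84.5%, substance use 56.2%, mood 38.7%,
#' antisocial personality 24.5%) with an odds-multiplier comorbidity
#' adjustment; item omission; and paired-rater perturbation.
#'
#' General-recidivism coefficients are not published; the defaults are
#' calibrated so that the simulated 5- and 10-year general rates match the
#' published base rates (8.8% and 13.2%) at the cohort mean score, with a
#' slope chosen for moderate discrimination.
#'
#' @param n_subjects cohort size.
#' @param prop_male proportion male.
#' @param score_model named list (`male`, `female`), each `c(mean=, sd=)`.
#' @param outcome_models nested list `outcome -> horizon (years, as
#'   character) -> c(b0=, b1=)` of log-odds intercept and per-point slope.
#' @param follow_up_mixture data.frame with columns `weight`, `lo`, `hi`:
#'   follow-up years drawn from a mixture of uniforms. The default places
#'   ~15% of follow-ups below 5 years and most of the rest beyond 10,
#'   mirroring validation-cohort denominators that shrink markedly at the
#'   5-year window but barely between 5 and 10.
#' @param diagnosis_prevalence named proportions.
#' @param comorbidity_or named pairwise odds multipliers, names like
#'   `"aspd:sud"`; pairs not listed are independent. The default elevates
#'   antisocial personality x substance use (odds ratio ~3.6, the only
#'   clearly non-independent published pairing).
#' @param missing_item_rate per-item omission probability for
#'   [generate_item_sheets()].
#' @param rater_disagreement per-item probability that a second rater
#'   scores differently; `rater_magnitude` is the maximum absolute weight
#'   perturbation.
#' @param seed integer master seed; all sub-streams derive from it.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(
    n_subjects = 478L,
    prop_male = 0.831,
    score_model = list(male = c(mean = -4.81, sd = 19.1),
                       female = c(mean = -16.61, sd = 14.9)),
    outcome_models = list(
      violent = list(`5` = c(b0 = -2.856, b1 = 0.040),
                     `10` = c(b0 = -2.471, b1 = 0.041)),
      general = list(`5` = c(b0 = -2.110, b1 = 0.033),
                     `10` = c(b0 = -1.656, b1 = 0.033))
    ),
    follow_up_mixture = data.frame(
      weight = c(0.15, 0.01, 0.84),
      lo = c(0.5, 5, 10), hi = c(5, 10, 40)),
    diagnosis_prevalence = c(psychotic = 0.845, sud = 0.562,
                             mood = 0.387, aspd = 0.245),
    comorbidity_or = c("aspd:sud" = 3.6),
    missing_item_rate = 0.02,
    rater_disagreement = 0.1,
    rater_magnitude = 1L,
    seed = 20221L) {
  stopifnot(n_subjects >= 1, prop_male >= 0, prop_male <= 1,
            missing_item_rate >= 0, missing_item_rate <= 1,
            rater_disagreement >= 0, rater_disagreement <= 1,
            rater_magnitude >= 1)
  for (sx in c("male", "female")) {
    m <- score_model[[sx]]
    if (is.null(m) || is.na(m["mean"]) || is.na(m["sd"]) || m["sd"] <= 0) {
      stop("score_model$", sx, " must supply mean and sd > 0")
    }
  }
  for (oc in names(outcome_models)) {
    hs <- outcome_models[[oc]]
    if (length(hs) == 0L) stop("outcome '", oc, "' has no horizon models")
    h_num <- suppressWarnings(as.numeric(names(hs)))
    if (anyNA(h_num) || any(h_num <= 0)) {
      stop("outcome '", oc, "': horizons must be positive numbers")
    }
    for (h in names(hs)) {
      cf <- hs[[h]]
      if (anyNA(cf[c("b0", "b1")])) {
        stop("outcome '", oc, "' horizon ", h, ": b0/b1 missing")
      }
    }
  }
  stopifnot(all(diagnosis_prevalence >= 0), all(diagnosis_prevalence <= 1),
            all(follow_up_mixture$weight >= 0),
            all(follow_up_mixture$hi > follow_up_mixture$lo))
  structure(
    list(n_subjects = as.integer(n_subjects), prop_male = prop_male,
         score_model = score_model, outcome_models = outcome_models,
         follow_up_mixture = follow_up_mixture,
         diagnosis_prevalence = diagnosis_prevalence,
         comorbidity_or = comorbidity_or,
         missing_item_rate = missing_item_rate,
         rater_disagreement = rater_disagreement,
         rater_magnitude = as.integer(rater_magnitude),
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

# deterministic sub-seed per named stream; keeps components decoupled so
# e.g. adding diagnoses does not shift the score stream
sub_seed <- function(seed, stream) {
  streams <- c(sex = 1L, score = 2L, follow_up = 3L, outcome = 4L,
               diagnosis = 5L, sheets = 6L, rater = 7L)
  k <- streams[[stream]]
  as.integer((as.double(seed) * 48271 + k * 1000003) %% 2147483647)
}

# analytic mean/sd of a normal truncated to [a, b]
trunc_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  dphi <- stats::dnorm(al) - stats::dnorm(be)
  m <- mu + sigma * dphi / z
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z -
                    (dphi / z)^2)
  c(mean = m, sd = sqrt(v))
}

# latent (mu, sigma) such that the TRUNCATED distribution attains the
# printed mean/SD: published moments describe the observed (range-limited)
# scores, so matching them requires solving the inverse problem
trunc_normal_params <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    m <- trunc_moments(p[1], exp(p[2]), a, b)
    (m[["mean"]] - target_mean)^2 + (m[["sd"]] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  if (fit$value > 1e-6) {
    warning("truncated-normal moment matching residual ",
            signif(sqrt(fit$value), 3),
            "; printed moments may be unattainable within the score range")
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# integer scores from a moment-matched truncated normal via inverse-CDF
r_trunc_score <- function(n, mean, sd, lo, hi) {
  par <- trunc_normal_params(mean, sd, lo - 0.5, hi + 0.5)
  plo <- stats::pnorm(lo - 0.5, par[["mu"]], par[["sigma"]])
  phi <- stats::pnorm(hi + 0.5, par[["mu"]], par[["sigma"]])
  u <- stats::runif(n, plo, phi)
  x <- round_half_away(stats::qnorm(u, par[["mu"]], par[["sigma"]]))
  as.integer(pmin(pmax(x, lo), hi))
}

# piecewise-linear event-time CDF through (0,0) and (h_k, p_k) for the
# configured horizons; exact window probabilities at every horizon
draw_event_times <- function(score, coefs) {
  h <- as.numeric(names(coefs))
  o <- order(h)
  h <- h[o]; coefs <- coefs[o]
  p <- vapply(coefs, function(cf) {
    stats::plogis(cf[["b0"]] + cf[["b1"]] * score)
  }, numeric(length(score)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (ncol(p) > 1L && any(apply(p, 1, function(r) any(diff(r) < 0)))) {
    stop("outcome model probabilities must be non-decreasing in horizon")
  }
  n <- length(score)
  p_max <- p[, ncol(p)]
  u <- stats::runif(n)
  event <- u < p_max
  time <- rep(NA_real_, n)
  knot_h <- c(0, h)
  for (i in which(event)) {
    knot_p <- c(0, p[i, ])
    seg <- findInterval(u[i], knot_p, rightmost.closed = TRUE)
    seg <- min(seg, length(h))
    span_p <- knot_p[seg + 1L] - knot_p[seg]
    frac <- if (span_p > 0) (u[i] - knot_p[seg]) / span_p else stats::runif(1)
    time[i] <- knot_h[seg] + frac * (knot_h[seg + 1L] - knot_h[seg])
  }
  list(event = event, time = time)
}

# joint cell p11 for two Bernoullis with margins p1, p2 and odds ratio psi
pair_p11 <- function(p1, p2, psi) {
  if (abs(psi - 1) < 1e-12) return(p1 * p2)
  s <- 1 + (p1 + p2) * (psi - 1)
  p11 <- (s - sqrt(s^2 - 4 * psi * (psi - 1) * p1 * p2)) /
    (2 * (psi - 1))
  min(max(p11, max(0, p1 + p2 - 1)), min(p1, p2))
}

# marginal draws, then each configured pair's two columns are redrawn
# jointly from the odds-multiplier-consistent bivariate law (margins kept
# exact). A diagnosis appearing in several pairs takes the last pair's
# law; printed pairwise rates are targets, not guarantees.
draw_diagnoses <- function(n, prev, or) {
  labs <- names(prev)
  x <- matrix(stats::rbinom(n * length(prev), 1L, rep(prev, each = n)),
              nrow = n, dimnames = list(NULL, labs))
  for (j in seq_along(or)) {
    p <- strsplit(names(or)[j], ":", fixed = TRUE)[[1]]
    if (length(p) != 2L || !all(p %in% labs)) {
      stop("comorbidity pair references unknown diagnosis: ", names(or)[j])
    }
    p1 <- prev[[p[1]]]; p2 <- prev[[p[2]]]
    p11 <- pair_p11(p1, p2, or[[j]])
    cell <- sample.int(4L, n, replace = TRUE,
                       prob = c(p11, p1 - p11, p2 - p11,
                                1 - p1 - p2 + p11))
    x[, p[1]] <- as.integer(cell %in% c(1L, 2L))
    x[, p[2]] <- as.integer(cell %in% c(1L, 3L))
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws sex, an integer total score from the sex-specific truncated-normal
#' model, a follow-up length, risk-bin assignment, diagnoses, and per-outcome
#' recidivism events with conviction times. Event times follow the
#' piecewise-linear law interpolating the configured per-horizon logistic
#' probabilities, so the probability of an event inside each configured
#' window equals `plogis(b0 + b1 * score)` for that window exactly. Events
#' whose latent time exceeds the follow-up are censored (flag 0, no time).
#'
#' Identical `params$seed` yields identical cohorts.
#'
#' @param params [simulation_params()].
#' @param spec [instrument_spec()].
#' @return data.frame of class `cohort` with one row per subject:
#'   `subject_id`, `sex`, diagnosis indicator columns, `total`, `bin`,
#'   `follow_up_years`, and per outcome `<outcome>_event` /
#'   `<outcome>_time` columns.
#' @export
generate_cohort <- function(params, spec = default_instrument_spec()) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(spec, "instrument_spec"))
  n <- params$n_subjects

  set.seed(sub_seed(params$seed, "sex"))
  sex <- ifelse(stats::runif(n) < params$prop_male, "male", "female")

  set.seed(sub_seed(params$seed, "score"))
  total <- integer(n)
  for (sx in c("male", "female")) {
    i <- sex == sx
    m <- params$score_model[[sx]]
    total[i] <- r_trunc_score(sum(i), m[["mean"]], m[["sd"]],
                              spec$min_total, spec$max_total)
  }

  set.seed(sub_seed(params$seed, "follow_up"))
  mix <- params$follow_up_mixture
  comp <- sample.int(nrow(mix), n, replace = TRUE,
                     prob = mix$weight / sum(mix$weight))
  follow_up <- stats::runif(n, mix$lo[comp], mix$hi[comp])

  set.seed(sub_seed(params$seed, "diagnosis"))
  dx <- draw_diagnoses(n, params$diagnosis_prevalence, params$comorbidity_or)

  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    sex = sex, stringsAsFactors = FALSE)
  for (lab in colnames(dx)) out[[paste0("dx_", lab)]] <- as.integer(dx[, lab])
  out$total <- total
  out$bin <- assign_bin(total, spec)
  out$follow_up_years <- follow_up

  set.seed(sub_seed(params$seed, "outcome"))
  for (oc in names(params$outcome_models)) {
    et <- draw_event_times(total, params$outcome_models[[oc]])
    observed <- et$event & !is.na(et$time) & et$time <= follow_up
    out[[paste0(oc, "_event")]] <- as.integer(observed)
    out[[paste0(oc, "_time")]] <- ifelse(observed, et$time, NA_real_)
  }
  class(out) <- c("cohort", "data.frame")
  out
}

# random feasible decomposition of a total into per-item weights; allowed
# sets are scanned greedily after a uniform initial draw
decompose_total <- function(total, spec) {
  w <- vapply(spec$items, function(it) sample(it$allowed_weights, 1L),
              integer(1))
  diff <- total - sum(w)
  n_items <- length(w)
  guard <- 0L
  while (diff != 0L && guard < 1000L) {
    ord <- sample.int(n_items)
    moved <- FALSE
    for (j in ord) {
      aw <- spec$items[[j]]$allowed_weights
      if (diff > 0L) {
        cand <- aw[aw > w[j] & aw <= w[j] + diff]
        if (length(cand)) { w[j] <- max(cand); moved <- TRUE }
      } else {
        cand <- aw[aw < w[j] & aw >= w[j] + diff]
        if (length(cand)) { w[j] <- min(cand); moved <- TRUE }
      }
      diff <- total - sum(w)
      if (diff == 0L) break
    }
    if (!moved) break
    guard <- guard + 1L
  }
  if (diff != 0L) stop("cannot decompose total ", total, " over item sets")
  w
}

#' Generate item-level score sheets for a cohort
#'
#' Each subject's total is decomposed into a random feasible per-item weight
#' vector (so sheet totals before omission equal the cohort totals), then
#' each item is independently omitted with `missing_item_rate`, capped at
#' `spec$max_missing` omissions per sheet.
#'
#' @param cohort from [generate_cohort()].
#' @inheritParams generate_cohort
#' @return score-sheet data.frame (see [validate_sheets()]).
#' @export
generate_item_sheets <- function(cohort, spec, params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(sub_seed(params$seed, "sheets"))
  n <- nrow(cohort)
  w <- t(vapply(cohort$total, decompose_total, integer(length(spec$items)),
                spec = spec))
  colnames(w) <- spec$item_names
  sheets <- data.frame(subject_id = cohort$subject_id,
                       stringsAsFactors = FALSE)
  sheets <- cbind(sheets, as.data.frame(w))
  rate <- params$missing_item_rate
  if (rate > 0) {
    for (i in seq_len(n)) {
      drop <- which(stats::runif(length(spec$items)) < rate)
      if (length(drop) > spec$max_missing) {
        drop <- sample(drop, spec$max_missing)
      }
      if (length(drop)) sheets[i, spec$item_names[drop]] <- NA_integer_
    }
  }
  sheets
}

#' Generate a second rater's score sheets
#'
#' Re-scores each (non-missing) item: with probability
#' `1 - rater_disagreement` the weight is copied; otherwise it is perturbed
#' by a uniform draw from `{-magnitude, ..., -1, 1, ..., magnitude}`,
#' clamped to the item's allowed set (a perturbation clamped back onto the
#' original weight is reflected to the other side where possible).
#'
#' @param sheets first-rater sheets.
#' @inheritParams generate_cohort
#' @export
generate_rater_pair <- function(sheets, spec, params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(sub_seed(params$seed, "rater"))
  out <- sheets
  p <- params$rater_disagreement
  mag <- params$rater_magnitude
  for (j in seq_along(spec$items)) {
    it <- spec$items[[j]]
    v <- sheets[[it$name]]
    hit <- !is.na(v) & stats::runif(length(v)) < p
    for (i in which(hit)) {
      if (p >= 1 && mag >= diff(range(it$allowed_weights))) {
        # full-disagreement stress mode: uniform re-draw over the set
        out[i, it$name] <- sample(it$allowed_weights, 1L)
        next
      }
      step <- sample(c(-seq_len(mag), seq_len(mag)), 1L)
      cand <- v[i] + step
      aw <- it$allowed_weights
      cand <- aw[which.min(abs(aw - cand))]
      if (cand == v[i]) {
        alt <- v[i] - step
        cand <- aw[which.min(abs(aw - alt))]
      }
      out[i, it$name] <- cand
    }
  }
  out
}

#' Write / read a cohort as delimited text
#'
#' @param cohort a `cohort` data.frame.
#' @param path file path; plain comma-separated text with header.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "sex", "total", "bin", "follow_up_years")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("cohort file missing columns: ",
                         paste(miss, collapse = ", "))
  class(x) <- c("cohort", "data.frame")
  x
}
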