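# shared fixture builders; everything is generated in code, seeded

tiny_spec <- function() {
  # three items, bins tiling [-4, 6] in three intervals
  instrument_spec(
    list(item_def("a", -2:2), item_def("b", -1:1), item_def("c", -1:3)),
    bin_lower = c(-4L, 0L, 3L),
    bin_upper = c(-1L, 2L, 6L),
    max_missing = 1L
  )
}

default_spec <- default_instrument_spec()

sheet_df <- function(spec, weights, id = "s1") {
  stopifnot(length(weights) == length(spec$items))
  df <- as.data.frame(as.list(stats::setNames(weights, spec$item_names)))
  cbind(data.frame(subject_id = id, stringsAsFactors = FALSE), df)
}

small_cohort <- function(n = 400, seed = 11, ...) {
  generate_cohort(simulation_params(n_subjects = n, seed = seed, ...),
                  default_spec)
}

# exhaustive pair-counting AUC oracle (ties counted 1/2)
auc_brute <- function(scores, outcomes) {
  s1 <- scores[outcomes == 1]
  s0 <- scores[outcomes == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# coarse-to-fine grid-search maximizer of the logistic log-likelihood,
# independent of the IRLS path
grid_logistic <- function(scores, outcomes) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * scores
    sum(outcomes * eta - log1p(exp(eta)))
  }
  b0r <- seq(-6, 2, length.out = 41)
  b1r <- seq(-0.5, 0.5, length.out = 41)
  for (pass in 1:8) {
    vals <- outer(b0r, b1r, Vectorize(ll))
    ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    b0 <- b0r[ij[1]]; b1 <- b1r[ij[2]]
    w0 <- diff(range(b0r)) / 8
    w1 <- diff(range(b1r)) / 8
    b0r <- seq(b0 - w0, b0 + w0, length.out = 41)
    b1r <- seq(b1 - w1, b1 + w1, length.out = 41)
  }
  c(b0 = b0, b1 = b1)
}
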