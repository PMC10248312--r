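#' Item definition for an actuarial instrument
#'
#' An item carries a finite set of allowed integer weights. Published
#' descriptions of actuarial tools typically print only each item's weight
#' *range*; by default the allowed set is every integer in that range, and a
#' sparser set can be supplied explicitly when the scoring manual is
#' available.
#'
#' @param name item label.
#' @param allowed_weights finite set of integer weights the item may take.
#' @return an object of class `item_def` with fields `name`,
#'   `allowed_weights`, `min_weight`, `max_weight`.
#' @export
item_def <- function(name, allowed_weights) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  w <- as.integer(allowed_weights)
  if (length(w) < 1L || anyNA(w)) {
    stop("item '", name, "': allowed_weights must be a non-empty integer set")
  }
  w <- sort(unique(w))
  structure(
    list(name = name, allowed_weights = w,
         min_weight = min(w), max_weight = max(w)),
    class = "item_def"
  )
}

#' Instrument specification: items, risk bins, proration policy
#'
#' Bundles the ordered item list, the ordered risk-bin intervals over the
#' total-score range, and the maximum number of omitted items that may be
#' prorated.
#'
#' @param items list of [item_def()] objects.
#' @param bin_lower,bin_upper integer vectors of the same length giving the
#'   inclusive lower/upper edge of each risk bin; jointly they must tile the
#'   total-score range `[sum of item minima, sum of item maxima]` with no
#'   gaps or overlaps.
#' @param max_missing maximum number of omitted items eligible for proration
#'   (default 4).
#' @return an object of class `instrument_spec`.
#' @seealso [default_instrument_spec()], [total_score()], [assign_bin()]
#' @export
instrument_spec <- function(items, bin_lower, bin_upper, max_missing = 4L) {
  stopifnot(is.list(items), length(items) >= 1L)
  for (it in items) {
    if (!inherits(it, "item_def")) stop("items must be item_def objects")
  }
  nms <- vapply(items, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate item names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  bin_lower <- as.integer(bin_lower)
  bin_upper <- as.integer(bin_upper)
  stopifnot(length(bin_lower) == length(bin_upper), length(bin_lower) >= 1L)
  if (any(bin_upper < bin_lower)) stop("bin upper edge below lower edge")
  min_total <- sum(vapply(items, `[[`, integer(1), "min_weight"))
  max_total <- sum(vapply(items, `[[`, integer(1), "max_weight"))
  if (bin_lower[1] != min_total || bin_upper[length(bin_upper)] != max_total) {
    stop("bins must cover the total-score range [", min_total, ", ",
         max_total, "]")
  }
  if (length(bin_lower) > 1L &&
      any(bin_lower[-1L] != bin_upper[-length(bin_upper)] + 1L)) {
    stop("bin intervals must be adjacent, disjoint and ordered")
  }
  max_missing <- as.integer(max_missing)
  stopifnot(max_missing >= 0L, max_missing < length(items))
  structure(
    list(items = items, item_names = nms,
         bins = data.frame(bin = seq_along(bin_lower),
                           lower = bin_lower, upper = bin_upper),
         min_total = min_total, max_total = max_total,
         max_missing = max_missing),
    class = "instrument_spec"
  )
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat("<instrument_spec> ", length(x$items), " items, total range [",
      x$min_total, ", ", x$max_total, "], ", nrow(x$bins),
      " bins, max ", x$max_missing, " proratable omissions\n", sep = "")
  invisible(x)
}

# The 12 published item weight ranges for the revised violence risk
# appraisal guide (VRAG-R).  Allowed sets default to all integers in range.
vragr_items <- function() {
  rng <- list(
    lived_with_parents_to_16       = c(-2L, 2L),
    elementary_school_maladjustment = c(-3L, 4L),
    alcohol_drug_problems          = c(-2L, 4L),
    marital_status_at_index        = c(-1L, 1L),
    nonviolent_criminal_history    = c(-3L, 5L),
    failure_on_conditional_release = c(-2L, 4L),
    age_at_index_offense           = c(-7L, 2L),
    violent_criminal_history       = c(-2L, 4L),
    prior_correctional_admissions  = c(-2L, 6L),
    conduct_disorder_before_15     = c(-2L, 5L),
    sex_offending_history          = c(-2L, 3L),
    antisociality                  = c(-6L, 6L)
  )
  mapply(function(nm, r) item_def(nm, seq(r[1], r[2])),
         names(rng), rng, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Default VRAG-R instrument specification
#'
#' Twelve items whose printed weight ranges sum to a total score between
#' -34 and +46, nine ordered risk bins, and proration of up to four omitted
#' items.
#'
#' Two published nine-bin layouts differ in whether -25 belongs to bin 1 or
#' bin 2. `layout = "norms"` (default) puts -25 in bin 1 (bin 2 starts at
#' -24), matching the layout used with the normative expected-rate tables;
#' `layout = "descriptive"` starts bin 2 at -25. Calibration against a norms
#' table must use the norms' own layout.
#'
#' @param layout `"norms"` (bin 1 is `<= -25`) or `"descriptive"`
#'   (bin 1 is `< -25`).
#' @return an [instrument_spec()].
#' @export
default_instrument_spec <- function(layout = c("norms", "descriptive")) {
  layout <- match.arg(layout)
  items <- vragr_items()
  if (layout == "norms") {
    lower <- c(-34L, -24L, -18L, -13L, -7L, 6L, 13L, 19L, 28L)
  } else {
    lower <- c(-34L, -25L, -18L, -13L, -7L, 6L, 13L, 19L, 28L)
  }
  upper <- c(lower[-1L] - 1L, 46L)
  instrument_spec(items, lower, upper, max_missing = 4L)
}

#' Read / write an instrument specification as JSON
#'
#' The config carries item names with their allowed weight sets, bin edges,
#' and the proration cap, so a non-default instrument (or a sparser allowed
#' set from a scoring manual) can be supplied without code changes.
#'
#' @param path file path.
#' @return `read_instrument_spec()` returns an [instrument_spec()];
#'   `write_instrument_spec()` returns `path` invisibly.
#' @export
read_instrument_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("items", "bin_lower", "bin_upper", "max_missing")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("instrument config missing fields: ",
                         paste(miss, collapse = ", "))
  items <- mapply(item_def, names(cfg$items), cfg$items, SIMPLIFY = FALSE)
  instrument_spec(items, cfg$bin_lower, cfg$bin_upper, cfg$max_missing)
}

#' @rdname read_instrument_spec
#' @param spec an [instrument_spec()].
#' @export
write_instrument_spec <- function(spec, path) {
  stopifnot(inherits(spec, "instrument_spec"))
  cfg <- list(
    items = stats::setNames(
      lapply(spec$items, `[[`, "allowed_weights"), spec$item_names),
    bin_lower = spec$bins$lower,
    bin_upper = spec$bins$upper,
    max_missing = spec$max_missing
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Score sheets: per-subject item weights
#'
#' A score-sheet table has one row per subject, a `subject_id` column and
#' one integer column per instrument item; `NA` marks an omitted item.
#'
#' @param sheets a data.frame as described above.
#' @param spec an [instrument_spec()].
#' @return the validated data.frame (invisibly for the validator).
#' @export
validate_sheets <- function(sheets, spec) {
  stopifnot(is.data.frame(sheets), inherits(spec, "instrument_spec"))
  miss <- setdiff(c("subject_id", spec$item_names), names(sheets))
  if (length(miss)) stop("score sheets missing columns: ",
                         paste(miss, collapse = ", "))
  for (it in spec$items) {
    v <- sheets[[it$name]]
    bad <- !is.na(v) & !(v %in% it$allowed_weights)
    if (any(bad)) {
      stop("item '", it$name, "': weight ", v[which(bad)[1]],
           " outside allowed set {",
           paste(it$allowed_weights, collapse = ","), "}")
    }
  }
  all_missing <- rowSums(!is.na(as.matrix(sheets[spec$item_names]))) == 0L
  if (any(all_missing)) stop("sheet with no scored items: subject ",
                             sheets$subject_id[which(all_missing)[1]])
  invisible(sheets)
}

#' Read score sheets from delimited text
#'
#' Empty fields or the string `"NA"` encode omitted items.
#'
#' @inheritParams validate_sheets
#' @param path delimited text file with header.
#' @param sep field separator (default comma).
#' @export
read_score_sheets <- function(path, spec, sep = ",") {
  sheets <- utils::read.table(path, header = TRUE, sep = sep,
                              na.strings = c("", "NA"),
                              stringsAsFactors = FALSE)
  validate_sheets(sheets, spec)
  sheets
}

#' Unprorated total score
#'
#' Sums the non-missing item weights per sheet and reports how many items
#' were omitted.
#'
#' @inheritParams validate_sheets
#' @return data.frame with `subject_id`, `total` (sum of scored items) and
#'   `n_missing`.
#' @export
total_score <- function(sheets, spec) {
  validate_sheets(sheets, spec)
  m <- as.matrix(sheets[spec$item_names])
  data.frame(
    subject_id = sheets$subject_id,
    total = as.integer(rowSums(m, na.rm = TRUE)),
    n_missing = as.integer(rowSums(is.na(m)))
  )
}

#' Prorate omitted items
#'
#' With `m` omitted items (1 <= m <= `max_missing`), the prorated total adds
#' `m` times the mean weight of the scored items to the unprorated total,
#' i.e. the omitted items are imputed at the scored-item average. Sheets
#' with nothing missing pass through unchanged; more than `max_missing`
#' omissions is an error.
#'
#' @inheritParams validate_sheets
#' @return data.frame with `subject_id`, `total` (unprorated), `n_missing`,
#'   `adjustment`, and `total_prorated` (real-valued; see
#'   [round_half_away()] and [assign_bin()] for bin lookup).
#' @export
prorate <- function(sheets, spec) {
  ts <- total_score(sheets, spec)
  over <- ts$n_missing > spec$max_missing
  if (any(over)) {
    stop("too many omitted items to prorate (subject ",
         ts$subject_id[which(over)[1]], ": ", ts$n_missing[which(over)[1]],
         " missing, cap ", spec$max_missing, ")")
  }
  n_items <- length(spec$items)
  mean_scored <- ts$total / (n_items - ts$n_missing)
  adj <- ifelse(ts$n_missing > 0L, ts$n_missing * mean_scored, 0)
  data.frame(
    subject_id = ts$subject_id,
    total = ts$total,
    n_missing = ts$n_missing,
    adjustment = adj,
    total_prorated = ts$total + adj
  )
}

#' Round half away from zero
#'
#' Bins are defined on integers; fractional prorated totals are rounded
#' half-away-from-zero (2.5 -> 3, -2.5 -> -3) before bin lookup, unlike
#' base R's banker's rounding.
#'
#' @param x numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assign risk bins to total scores
#'
#' @param total numeric vector of total scores. Fractional values (from
#'   proration) are rounded half-away-from-zero first.
#' @param spec an [instrument_spec()].
#' @return integer vector of bin numbers.
#' @export
assign_bin <- function(total, spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  t_int <- round_half_away(total)
  out_of_range <- !is.na(t_int) &
    (t_int < spec$min_total | t_int > spec$max_total)
  if (any(out_of_range)) {
    stop("total score ", total[which(out_of_range)[1]],
         " outside instrument range [", spec$min_total, ", ",
         spec$max_total, "]")
  }
  idx <- findInterval(t_int, spec$bins$lower)
  as.integer(spec$bins$bin[idx])
}
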