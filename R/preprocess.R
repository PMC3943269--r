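#' Quartile categorization of a continuous variable
#'
#' Divides a numeric variable into 4 categories comprising a similar number
#' of observations, the coding used throughout the analysis for weather
#' summaries, environmental exposures, and the risk score. Assignment is
#' rank-based (average ranks), with ties at a boundary going to the lower
#' category, so the result is invariant to strictly increasing transforms and
#' category sizes differ by at most 1 in the absence of ties.
#'
#' @param x numeric vector with at least 4 distinct non-missing values.
#' @param coding optionally, a `quartile_coding` from a previous call: `x` is
#'   then cut at the stored value cutoffs instead of being re-ranked, so a
#'   coding learned on one cohort reproduces itself exactly on the same data.
#' @return an integer vector of categories 1-4 with the `quartile_coding`
#'   (cutoffs = maximum value observed in categories 1-3) attached as
#'   attribute `"coding"`; retrieve it with [quartile_coding()].
#' @examples
#' q <- quartile_categorize(1:8)
#' as.integer(q)
#' quartile_coding(q)
#' @export
quartile_categorize <- function(x, coding = NULL) {
  if (!is.numeric(x)) {
    abort_recwalk("`x` must be numeric.", "invalid_argument")
  }
  if (anyNA(x)) {
    abort_recwalk("`x` must not contain missing values.", "invalid_argument")
  }
  if (!is.null(coding)) {
    return(apply_quartile_coding(x, coding))
  }
  if (length(unique(x)) < 4L) {
    abort_recwalk(
      "quartile categorization needs at least 4 distinct values.",
      "degenerate_variable"
    )
  }
  n <- length(x)
  r <- rank(x, ties.method = "average")
  cat <- 1L + pmin(3L, as.integer(floor(4 * (r - 1) / n)))
  cutoffs <- vapply(1:3, function(k) max(x[cat == k]), numeric(1))
  coding <- structure(
    list(cutoffs = cutoffs, labels = paste0("Q", 1:4)),
    class = "quartile_coding"
  )
  structure(cat, coding = coding)
}

#' @rdname quartile_categorize
#' @param q a vector returned by [quartile_categorize()].
#' @export
quartile_coding <- function(q) attr(q, "coding")

#' @rdname quartile_categorize
#' @export
apply_quartile_coding <- function(x, coding) {
  if (!inherits(coding, "quartile_coding")) {
    abort_recwalk("`coding` must be a quartile_coding.", "invalid_argument")
  }
  cat <- 1L + (x > coding$cutoffs[1]) + (x > coding$cutoffs[2]) +
    (x > coding$cutoffs[3])
  structure(as.integer(cat), coding = coding)
}

#' @export
print.quartile_coding <- function(x, ...) {
  cat("<quartile_coding> cutoffs:", format(x$cutoffs, digits = 6), "\n")
  invisible(x)
}

#' Code reported walking minutes as the 5-category ordinal outcome
#'
#' Category 1 corresponds to zero reported neighborhood walking minutes; the
#' positive values are divided into quartile categories 2-5 comprising a
#' similar number of participants.
#'
#' @param minutes nonnegative numeric vector of reported walking minutes with
#'   at least 4 distinct positive values.
#' @return integer vector of categories 1-5.
#' @examples
#' code_ordinal_walking(c(0, 0, 10, 20, 30, 40))
#' @export
code_ordinal_walking <- function(minutes) {
  if (!is.numeric(minutes) || anyNA(minutes)) {
    abort_recwalk("`minutes` must be numeric without missing values.", "invalid_argument")
  }
  if (any(minutes < 0)) {
    abort_recwalk("walking minutes cannot be negative.", "invalid_argument")
  }
  pos <- minutes > 0
  if (!any(pos)) {
    abort_recwalk("all walking minutes are zero; the ordinal outcome is degenerate.",
                  "degenerate_outcome")
  }
  if (length(unique(minutes[pos])) < 4L) {
    abort_recwalk(
      "need at least 4 distinct positive walking times to form categories 2-5.",
      "degenerate_outcome"
    )
  }
  out <- integer(length(minutes))
  out[!pos] <- 1L
  out[pos] <- 1L + as.integer(quartile_categorize(minutes[pos]))
  out
}

#' Average a daily weather series over the 8-day recruitment window
#'
#' Weather exposure for a participant is the arithmetic mean of the daily
#' value over the recruitment day and the 7 previous days (8 calendar days in
#' total). All 8 days must be present in the series.
#'
#' @param daily a data frame with columns `date` (Date) and `value` (numeric).
#' @param recruitment_date a Date (or a vector of Dates; one mean per date).
#' @return numeric vector of 8-day window means, one per recruitment date.
#' @examples
#' daily <- tibble::tibble(
#'   date = as.Date("2007-03-01") + 0:10,
#'   value = 1:11
#' )
#' weather_window_average(daily, as.Date("2007-03-08"))
#' @export
weather_window_average <- function(daily, recruitment_date) {
  daily <- as.data.frame(daily)
  if (!all(c("date", "value") %in% names(daily))) {
    abort_recwalk("`daily` must have columns `date` and `value`.", "invalid_argument")
  }
  dates <- as.Date(daily$date)
  vals <- as.numeric(daily$value)
  recruitment_date <- as.Date(recruitment_date)
  vapply(recruitment_date, function(d) {
    window <- d - 7:0
    idx <- match(window, dates)
    if (anyNA(idx) || anyNA(vals[idx])) {
      abort_recwalk(
        sprintf("daily weather series is missing days in the 8-day window ending %s.", d),
        "missing_weather"
      )
    }
    mean(vals[idx])
  }, numeric(1))
}
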