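#' Canonical categorical levels of the line-listing schema
#'
#' Spontaneous-report line listings use fixed vocabularies for the
#' demographic and administrative fields. `age_bands()` returns the seven
#' ordinal age bands (plus `"unknown"`) used by WHO-style report tabulations;
#' the other helpers return the allowed levels of their field. `"unknown"` is
#' always an explicit category, never an `NA`, so that denominators over
#' known values remain auditable.
#'
#' @param include_unknown Include the explicit `"unknown"` level.
#' @return Character vector of levels, in canonical display order.
#' @export
age_bands <- function(include_unknown = TRUE) {
  x <- c("<=23mo", "2-11y", "12-17y", "18-44y", "45-64y", "65-74y", ">=75y")
  if (include_unknown) c(x, "unknown") else x
}

#' @rdname age_bands
#' @export
sex_levels <- function(include_unknown = TRUE) {
  x <- c("male", "female")
  if (include_unknown) c(x, "unknown") else x
}

#' @rdname age_bands
#' @export
reporter_levels <- function(include_unknown = TRUE) {
  x <- c("physician", "pharmacist", "other_health", "lawyer", "consumer")
  if (include_unknown) c(x, "unknown") else x
}

#' @rdname age_bands
#' @export
outcome_levels <- function(include_unknown = TRUE) {
  x <- c("recovered", "recovering_or_sequelae", "not_recovered")
  if (include_unknown) c(x, "unknown") else x
}

#' @rdname age_bands
#' @export
tristate_levels <- function() c("true", "false", "unknown")

#' Round half away from zero
#'
#' Printed pharmacovigilance tables round percentages to one decimal with
#' halves rounded away from zero (so 17.55 -> 17.6), unlike base R's
#' round-half-even. A small epsilon guards against floating-point
#' representations of exact halves.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a denominator, printed-table style
#'
#' Computes `100 * count / denominator` rounded to one decimal, half away
#' from zero — the arithmetic behind every "n (%)" cell in a report-count
#' table. Vectorised over both arguments.
#'
#' @param count Numerator count(s).
#' @param denominator Denominator count(s).
#' @param digits Decimal places (default 1, matching printed tables).
#' @return Numeric vector of percentages.
#' @examples
#' pct_of(4075, 11548) # 35.3
#' @export
pct_of <- function(count, denominator, digits = 1) {
  round_half_away(100 * count / denominator, digits)
}

# shared column order of the canonical line listing
ll_columns <- function() {
  c("report_id", "drug_codes", "reaction_terms", "age_group", "sex",
    "country", "reporter", "serious", "fatal", "outcome",
    "time_to_onset_days")
}

# fields whose "unknown"s count toward the de-duplication rule
unknownable_fields <- function() {
  c("age_group", "sex", "country", "reporter", "serious", "fatal", "outcome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
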