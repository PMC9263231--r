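#' Build a report set from vectors or a data frame
#'
#' A *report set* is a tibble with one row per individual case safety report
#' and the canonical columns `report_id`, `drug_codes` (list-column of
#' drug-code strings), `reaction_terms` (list-column of reaction-term
#' strings), `age_group`, `sex`, `country`, `reporter`, `serious`, `fatal`,
#' `outcome` (character with explicit `"unknown"`s) and
#' `time_to_onset_days` (non-negative integer, `NA` when missing).
#'
#' `as_report_set()` coerces a data frame to that shape — splitting
#' character `drug_codes`/`reaction_terms` cells on `sep`, filling absent
#' optional columns with `"unknown"`/`NA` — and validates it.
#'
#' @param x A data frame with at least `report_id`, `drug_codes` and
#'   `reaction_terms` columns.
#' @param sep Intra-cell separator used when multi-valued columns are given
#'   as single strings.
#' @return A validated report-set tibble.
#' @export
as_report_set <- function(x, sep = ";") {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  need <- c("report_id", "drug_codes", "reaction_terms")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  split_cell <- function(col) {
    if (is.list(col)) return(purrr::map(col, as.character))
    purrr::map(as.character(col), function(s) {
      if (is.na(s) || !nzchar(s)) return(character(0))
      v <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
      v[nzchar(v)]
    })
  }
  x$report_id <- as.character(x$report_id)
  x$drug_codes <- split_cell(x$drug_codes)
  x$reaction_terms <- split_cell(x$reaction_terms)
  for (f in unknownable_fields()) {
    if (!f %in% names(x)) x[[f]] <- "unknown"
    v <- as.character(x[[f]])
    v[is.na(v) | !nzchar(v)] <- "unknown"
    x[[f]] <- v
  }
  if (!"time_to_onset_days" %in% names(x)) x$time_to_onset_days <- NA_integer_
  x$time_to_onset_days <- as.integer(x$time_to_onset_days)
  x <- x[, ll_columns()]
  validate_reports(x)
  x
}

#' Validate a report-set tibble
#'
#' Checks the structural invariants of a report set: canonical columns,
#' non-empty drug and reaction sets, enumerated categorical values,
#' `fatal = "true"` implying `serious = "true"`, and non-negative
#' time-to-onset. Uniqueness of `report_id` is required only after
#' [deduplicate_reports()], so it is reported via `unique_ids` but not
#' enforced here.
#'
#' @param reports A report-set tibble.
#' @param require_unique_ids Error on duplicated `report_id`s.
#' @return `reports`, invisibly, if valid; otherwise an error.
#' @export
validate_reports <- function(reports, require_unique_ids = FALSE) {
  miss <- setdiff(ll_columns(), names(reports))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(reports$drug_codes) == 0)) {
    stop("every report must carry at least one drug code", call. = FALSE)
  }
  if (any(lengths(reports$reaction_terms) == 0)) {
    stop("every report must carry at least one reaction term", call. = FALSE)
  }
  chk <- list(age_group = age_bands(), sex = sex_levels(),
              reporter = reporter_levels(), outcome = outcome_levels(),
              serious = tristate_levels(), fatal = tristate_levels())
  for (f in names(chk)) {
    bad <- setdiff(unique(reports[[f]]), chk[[f]])
    if (length(bad) > 0) {
      stop("invalid ", f, " value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(reports$fatal == "true" & reports$serious != "true")) {
    stop("fatal reports must be serious", call. = FALSE)
  }
  tto <- reports$time_to_onset_days
  if (any(!is.na(tto) & tto < 0)) {
    stop("time_to_onset_days must be non-negative", call. = FALSE)
  }
  if (require_unique_ids && anyDuplicated(reports$report_id) > 0) {
    stop("duplicated report_id; run deduplicate_reports() first",
         call. = FALSE)
  }
  invisible(reports)
}

#' Read a line listing of individual case safety reports
#'
#' Reads the canonical comma-delimited line listing (UTF-8, header row, one
#' report per row; multi-valued drug/reaction cells separated by `sep`;
#' empty cells mapped to explicit `"unknown"`/missing). Rows lacking any
#' drug code or any reaction term, or carrying a value outside a field's
#' vocabulary, are rejected rather than silently kept; rejections are
#' reported with their row numbers in the `"rejections"` attribute and via a
#' message.
#'
#' @param path Path to the delimited file.
#' @param sep Intra-cell separator for multi-valued cells (default `";"`).
#' @param quiet Suppress the rejection message.
#' @return A report-set tibble with attributes `provenance` (source path)
#'   and `rejections` (tibble of `row`, `report_id`, `reason`).
#' @seealso [write_line_listing()], [as_report_set()]
#' @export
read_line_listing <- function(path, sep = ";", quiet = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  miss <- setdiff(ll_columns(), names(raw))
  if (length(miss) > 0) {
    stop("line listing is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, ll_columns()]
  n0 <- nrow(raw)
  split_cell <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    v <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
    v[nzchar(v)]
  }
  out <- tibble::tibble(
    report_id = as.character(raw$report_id),
    drug_codes = purrr::map(raw$drug_codes, split_cell),
    reaction_terms = purrr::map(raw$reaction_terms, split_cell)
  )
  for (f in unknownable_fields()) {
    v <- raw[[f]]
    v[is.na(v) | !nzchar(v)] <- "unknown"
    out[[f]] <- v
  }
  out$time_to_onset_days <- suppressWarnings(as.integer(raw$time_to_onset_days))

  chk <- list(age_group = age_bands(), sex = sex_levels(),
              reporter = reporter_levels(), outcome = outcome_levels(),
              serious = tristate_levels(), fatal = tristate_levels())
  reason <- rep(NA_character_, n0)
  take <- function(cond, why) {
    hit <- cond & is.na(reason)
    reason[hit] <<- why
  }
  take(is.na(out$report_id) | !nzchar(out$report_id), "missing report_id")
  take(lengths(out$drug_codes) == 0, "no drug codes")
  take(lengths(out$reaction_terms) == 0, "no reaction terms")
  for (f in names(chk)) {
    take(!out[[f]] %in% chk[[f]], paste("invalid", f))
  }
  take(!is.na(out$time_to_onset_days) & out$time_to_onset_days < 0,
       "negative time_to_onset_days")
  take(out$fatal == "true" & out$serious != "true",
       "fatal report not marked serious")

  rejections <- tibble::tibble(
    row = which(!is.na(reason)),
    report_id = out$report_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  out <- out[is.na(reason), ]
  if (!quiet && nrow(rejections) > 0) {
    message(nrow(rejections), " of ", n0,
            " row(s) rejected: ",
            paste(sprintf("row %d (%s)", rejections$row, rejections$reason),
                  collapse = "; "))
  }
  attr(out, "provenance") <- paste0("read from ", path)
  attr(out, "rejections") <- rejections
  validate_reports(out)
  out
}

#' Write a report set as a canonical line listing
#'
#' Emits the comma-delimited schema read by [read_line_listing()];
#' multi-valued cells are joined with `sep`, missing time-to-onset becomes
#' an empty cell. Reading the file back reproduces every field value.
#'
#' @param reports A report-set tibble.
#' @param path Output file path.
#' @param sep Intra-cell separator (default `";"`).
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(reports, path, sep = ";") {
  validate_reports(reports)
  flat <- tibble::as_tibble(reports)
  flat$drug_codes <- purrr::map_chr(reports$drug_codes, paste, collapse = sep)
  flat$reaction_terms <- purrr::map_chr(reports$reaction_terms, paste,
                                        collapse = sep)
  readr::write_csv(flat[, ll_columns()], path, na = "", progress = FALSE)
  invisible(path)
}

#' De-duplicate a report set by report identifier
#'
#' Spontaneous-reporting databases accumulate duplicate transmissions of the
#' same case; counts are always per unique report. Among rows sharing a
#' `report_id`, the row with the fewest unknown/missing fields (the most
#' complete record) is kept; ties are broken by first occurrence. The number
#' of rows removed is attached as attribute `"removed"` and reported with a
#' message.
#'
#' @param reports A report-set tibble.
#' @param quiet Suppress the removal message.
#' @return A report-set tibble with unique `report_id`s, in original order
#'   of the kept rows.
#' @export
deduplicate_reports <- function(reports, quiet = FALSE) {
  validate_reports(reports)
  unk <- rowSums(sapply(unknownable_fields(),
                        function(f) reports[[f]] == "unknown")) +
    is.na(reports$time_to_onset_days)
  ord <- seq_len(nrow(reports))
  keep <- tibble::tibble(report_id = reports$report_id, unk = unk, ord = ord) |>
    dplyr::group_by(.data$report_id) |>
    dplyr::slice_min(order_by = .data$unk, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(order_by = .data$ord, n = 1) |>
    dplyr::ungroup()
  out <- reports[sort(keep$ord), ]
  removed <- nrow(reports) - nrow(out)
  if (!quiet && removed > 0) {
    message(removed, " duplicate row(s) removed")
  }
  attr(out, "removed") <- removed
  attr(out, "provenance") <- attr(reports, "provenance")
  out
}

#' Select the case reports matching a case definition
#'
#' A *case* is any report whose reaction terms intersect the case-defining
#' term set (e.g. a MedDRA Preferred Term such as tubulointerstitial
#' nephritis). The input set is returned unmodified apart from row
#' filtering.
#'
#' @param reports A report-set tibble.
#' @param case_terms Non-empty character vector of case-defining reaction
#'   terms.
#' @return The subset of `reports` that are cases, original order preserved.
#' @export
select_cases <- function(reports, case_terms) {
  stopifnot(length(case_terms) > 0)
  hit <- purrr::map_lgl(reports$reaction_terms,
                        function(v) any(v %in% case_terms))
  out <- reports[hit, ]
  attr(out, "case_terms") <- case_terms
  out
}

#' Read or write a drug dictionary with ATC-style class paths
#'
#' The dictionary is comma-delimited with columns `drug_code`,
#' `display_name` and `atc_path`, the last a pipe-separated class path from
#' the anatomical main group down to (conventionally) the substance, e.g.
#' `"alimentary tract and metabolism|drugs for acid related disorders|proton
#' pump inhibitors|omeprazole"`. In memory `atc_path` is a list-column of
#' character vectors.
#'
#' @param path File path.
#' @return `read_drug_dictionary()`: a tibble with columns `drug_code`,
#'   `display_name`, `atc_path` (list-column). `write_drug_dictionary()`:
#'   `path`, invisibly.
#' @export
read_drug_dictionary <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("drug_code", "display_name", "atc_path")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("drug dictionary is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    drug_code = raw$drug_code,
    display_name = raw$display_name,
    atc_path = purrr::map(raw$atc_path,
                          function(s) trimws(strsplit(s, "|", fixed = TRUE)[[1]]))
  )
  validate_drug_dictionary(out)
  out
}

#' @rdname read_drug_dictionary
#' @param dictionary A drug-dictionary tibble.
#' @export
write_drug_dictionary <- function(dictionary, path) {
  validate_drug_dictionary(dictionary)
  flat <- tibble::tibble(
    drug_code = dictionary$drug_code,
    display_name = dictionary$display_name,
    atc_path = purrr::map_chr(dictionary$atc_path, paste, collapse = "|")
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

validate_drug_dictionary <- function(dictionary) {
  stopifnot(is.data.frame(dictionary))
  need <- c("drug_code", "display_name", "atc_path")
  miss <- setdiff(need, names(dictionary))
  if (length(miss) > 0) {
    stop("drug dictionary is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(dictionary$drug_code) > 0) {
    stop("drug_code must be unique in the dictionary", call. = FALSE)
  }
  if (any(lengths(dictionary$atc_path) == 0)) {
    stop("atc_path must be non-empty for every entry", call. = FALSE)
  }
  invisible(dictionary)
}
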