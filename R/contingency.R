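#' Build a 2x2 contingency table for one drug (or drug set) and a case
#' definition
#'
#' Cross-classifies every report in a de-duplicated database by whether it
#' mentions any of `drug_codes` (exposed) and whether it carries any of the
#' case-defining reaction terms (case). Counting is report-level: a report
#' mentioning two codes of the set still contributes once, so a class table
#' is the table of the *union* of its members' report sets, never a
#' cell-wise sum.
#'
#' @param db A de-duplicated report-set tibble (the full database).
#' @param case_terms Case-defining reaction terms.
#' @param drug_codes One code for a substance, several for a pooled class.
#' @param label Display label for the table (default: codes joined by "+").
#' @param dictionary Optional drug dictionary; codes absent from it trigger
#'   a warning but are still counted by literal match.
#' @return A one-row tibble with columns `label`, `a` (exposed cases), `b`
#'   (exposed non-cases), `c` (unexposed cases), `d` (unexposed non-cases).
#' @examples
#' db <- as_report_set(tibble::tibble(
#'   report_id = c("r1", "r2", "r3", "r4"),
#'   drug_codes = c("D", "D", "X", "X"),
#'   reaction_terms = c("E", "other", "E", "other")
#' ))
#' contingency_table(db, case_terms = "E", drug_codes = "D")
#' @export
contingency_table <- function(db, case_terms, drug_codes, label = NULL,
                              dictionary = NULL) {
  if (nrow(db) == 0) stop("empty report database", call. = FALSE)
  validate_reports(db, require_unique_ids = TRUE)
  stopifnot(length(case_terms) > 0, length(drug_codes) > 0)
  if (!is.null(dictionary)) {
    unknown <- setdiff(drug_codes, dictionary$drug_code)
    if (length(unknown) > 0) {
      warning("drug code(s) not in dictionary, counted by literal match: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  exposed <- purrr::map_lgl(db$drug_codes, function(v) any(v %in% drug_codes))
  case <- purrr::map_lgl(db$reaction_terms, function(v) any(v %in% case_terms))
  tibble::tibble(
    label = label %||% paste(drug_codes, collapse = "+"),
    a = sum(exposed & case),
    b = sum(exposed & !case),
    c = sum(!exposed & case),
    d = sum(!exposed & !case)
  )
}

#' Build contingency tables for every substance (and optionally every drug
#' class)
#'
#' One table per drug code appearing in at least one report and, when
#' `class_level` is given, one table per class label found at that depth of
#' the dictionary's ATC-style paths (codes missing from the dictionary, or
#' with a shorter path, contribute no class membership). All tables share
#' the margins `a + c = |cases|` and `a + b + c + d = |db|`.
#'
#' @inheritParams contingency_table
#' @param dictionary Optional drug dictionary tibble; used for display
#'   names and for class pooling.
#' @param class_level Optional 1-based depth into `atc_path` at which to
#'   pool classes (1 = anatomical main group).
#' @return A tibble with columns `label`, `drug_code` (`NA` for class
#'   rows), `level` (`"substance"` or `"class"`), `a`, `b`, `c`, `d`.
#' @export
contingency_tables <- function(db, case_terms, dictionary = NULL,
                               class_level = NULL) {
  if (nrow(db) == 0) stop("empty report database", call. = FALSE)
  validate_reports(db, require_unique_ids = TRUE)
  stopifnot(length(case_terms) > 0)
  n_db <- nrow(db)
  is_case <- purrr::map_lgl(db$reaction_terms,
                            function(v) any(v %in% case_terms))
  n_cases <- sum(is_case)

  long <- tibble::tibble(report_id = rep(db$report_id, lengths(db$drug_codes)),
                         is_case = rep(is_case, lengths(db$drug_codes)),
                         drug_code = unlist(db$drug_codes)) |>
    dplyr::distinct()

  subs <- long |>
    dplyr::group_by(.data$drug_code) |>
    dplyr::summarise(a = sum(.data$is_case), n_exposed = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(
      b = .data$n_exposed - .data$a,
      c = n_cases - .data$a,
      d = n_db - .data$n_exposed - .data$c,
      level = "substance"
    )
  if (!is.null(dictionary)) {
    subs <- subs |>
      dplyr::left_join(dictionary[, c("drug_code", "display_name")],
                       by = "drug_code") |>
      dplyr::mutate(label = dplyr::coalesce(.data$display_name,
                                            .data$drug_code)) |>
      dplyr::select(-"display_name")
  } else {
    subs$label <- subs$drug_code
  }
  out <- subs[, c("label", "drug_code", "level", "a", "b", "c", "d")]

  if (!is.null(class_level)) {
    if (is.null(dictionary)) {
      stop("class_level requires a drug dictionary", call. = FALSE)
    }
    cls_map <- tibble::tibble(
      drug_code = dictionary$drug_code,
      class = purrr::map_chr(dictionary$atc_path, function(p) {
        if (length(p) >= class_level) p[[class_level]] else NA_character_
      })
    ) |>
      dplyr::filter(!is.na(.data$class))
    cls <- long |>
      dplyr::inner_join(cls_map, by = "drug_code") |>
      dplyr::distinct(.data$report_id, .data$is_case, .data$class) |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(a = sum(.data$is_case), n_exposed = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(
        b = .data$n_exposed - .data$a,
        c = n_cases - .data$a,
        d = n_db - .data$n_exposed - .data$c,
        level = "class",
        label = .data$class,
        drug_code = NA_character_
      )
    out <- dplyr::bind_rows(out,
                            cls[, c("label", "drug_code", "level",
                                    "a", "b", "c", "d")])
  }
  stopifnot(all(out$a + out$c == n_cases),
            all(out$a + out$b + out$c + out$d == n_db))
  out
}

#' Export contingency tables as a delimited file
#'
#' @param tables Tibble from [contingency_table()] or
#'   [contingency_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contingency_tables <- function(tables, path) {
  keep <- intersect(c("label", "level", "a", "b", "c", "d"), names(tables))
  readr::write_csv(tables[, keep], path, progress = FALSE)
  invisible(path)
}
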