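#' Characterise a case cohort
#'
#' Produces the standard case-series characterisation of a report cohort:
#' age-band distribution (percentages among reports with known age), top
#' reporting countries, reporter qualifications, seriousness and fatality,
#' time-to-onset summary, most co-reported reaction terms (the
#' case-defining terms themselves excluded), and outcome distribution
#' (percentages among reports with a known outcome).
#'
#' Denominators differ by field, mirroring how report tabulations are
#' printed: age and outcome percentages are computed among known values;
#' country, reporter, seriousness, fatality and co-reported-term
#' percentages over all case reports. Every section records its denominator
#' explicitly so each percentage re-derives from its count. Percentages are
#' rounded to one decimal, half away from zero.
#'
#' @param cases A report-set tibble (the case cohort).
#' @param case_terms The case-defining reaction terms, excluded from the
#'   co-reported term ranking.
#' @param top_k_countries,top_k_terms How many countries / co-reported
#'   terms to keep.
#' @return An object of class `cohort_summary`: a list with `n_total` and
#'   tibbles `age`, `country`, `reporter`, `seriousness`, `tto`,
#'   `coreported`, `outcome`, each carrying `n`, `pct` and `denominator`
#'   columns.
#' @seealso [time_to_onset_summary()], [drug_report_shares()],
#'   [write_cohort_summary()]
#' @export
summarize_cohort <- function(cases, case_terms,
                             top_k_countries = 10, top_k_terms = 10) {
  if (nrow(cases) == 0) stop("empty case cohort", call. = FALSE)
  validate_reports(cases)
  n_total <- nrow(cases)

  count_level <- function(values, levels) {
    tibble::tibble(level = levels,
                   n = as.integer(table(factor(values, levels = levels))))
  }

  age <- count_level(cases$age_group, age_bands())
  n_age_known <- sum(age$n[age$level != "unknown"])
  age$denominator <- ifelse(age$level == "unknown", NA_integer_, n_age_known)
  age$pct <- ifelse(age$level == "unknown", NA_real_,
                    pct_of(age$n, n_age_known))

  country <- tibble::as_tibble(table(country = cases$country)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$country) |>
    dplyr::slice_head(n = top_k_countries) |>
    dplyr::mutate(n = as.integer(.data$n), denominator = n_total,
                  pct = pct_of(.data$n, n_total))

  reporter <- count_level(cases$reporter, reporter_levels()) |>
    dplyr::mutate(denominator = n_total, pct = pct_of(.data$n, n_total))

  n_serious <- sum(cases$serious == "true")
  n_fatal <- sum(cases$fatal == "true")
  seriousness <- tibble::tibble(
    level = c("serious", "fatal"),
    n = c(n_serious, n_fatal),
    denominator = n_total,
    pct = pct_of(c(n_serious, n_fatal), n_total)
  )

  tto <- time_to_onset_summary(cases)

  coreported <- tibble::tibble(report_id = rep(cases$report_id,
                                               lengths(cases$reaction_terms)),
                               term = unlist(cases$reaction_terms)) |>
    dplyr::filter(!.data$term %in% case_terms) |>
    dplyr::distinct() |>
    dplyr::count(.data$term, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$term) |>
    dplyr::slice_head(n = top_k_terms) |>
    dplyr::mutate(denominator = n_total, pct = pct_of(.data$n, n_total))

  outcome <- count_level(cases$outcome, outcome_levels())
  n_out_known <- sum(outcome$n[outcome$level != "unknown"])
  outcome$denominator <- ifelse(outcome$level == "unknown", NA_integer_,
                                n_out_known)
  outcome$pct <- ifelse(outcome$level == "unknown", NA_real_,
                        pct_of(outcome$n, n_out_known))

  structure(list(n_total = n_total, age = age, country = country,
                 reporter = reporter, seriousness = seriousness, tto = tto,
                 coreported = coreported, outcome = outcome,
                 case_terms = case_terms),
            class = "cohort_summary")
}

#' Median and interquartile range of time to onset
#'
#' Quantiles over reports with a known time-to-onset, using the
#' linear-interpolation quantile definition (`stats::quantile` type 7).
#'
#' @param cases A report-set tibble.
#' @return A one-row tibble `median`, `q1`, `q3`, `n_known`; all-`NA`
#'   quantiles when no report has a known time-to-onset.
#' @export
time_to_onset_summary <- function(cases) {
  tto <- cases$time_to_onset_days
  tto <- tto[!is.na(tto)]
  if (length(tto) == 0) {
    return(tibble::tibble(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          n_known = 0L))
  }
  q <- stats::quantile(tto, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3],
                 n_known = length(tto))
}

#' Report shares of substances or drug classes within a cohort
#'
#' Counts, for each substance (or each class at an ATC-path depth), the
#' case reports mentioning it — report-level, so a report carrying two
#' members of a class counts once for that class — and expresses each count
#' as a percentage of all case reports. Shares need not sum to 100 because
#' reports mention several drugs.
#'
#' @param cases A de-duplicated report-set tibble (the case cohort).
#' @param dictionary Optional drug dictionary (required for class levels;
#'   used for display names otherwise).
#' @param level `"substance"` (default) or a 1-based depth into the
#'   dictionary's `atc_path` (1 = anatomical main group).
#' @return A tibble `label`, `n`, `pct`, sorted by descending count (ties
#'   alphabetical).
#' @export
drug_report_shares <- function(cases, dictionary = NULL, level = "substance") {
  if (nrow(cases) == 0) stop("empty case cohort", call. = FALSE)
  validate_reports(cases, require_unique_ids = TRUE)
  n_total <- nrow(cases)
  long <- tibble::tibble(report_id = rep(cases$report_id,
                                         lengths(cases$drug_codes)),
                         drug_code = unlist(cases$drug_codes)) |>
    dplyr::distinct()
  if (identical(level, "substance")) {
    out <- long |> dplyr::count(.data$drug_code, name = "n")
    if (!is.null(dictionary)) {
      out <- out |>
        dplyr::left_join(dictionary[, c("drug_code", "display_name")],
                         by = "drug_code") |>
        dplyr::mutate(label = dplyr::coalesce(.data$display_name,
                                              .data$drug_code))
    } else {
      out$label <- out$drug_code
    }
  } else {
    stopifnot(is.numeric(level), level >= 1)
    if (is.null(dictionary)) {
      stop("class-level shares require a drug dictionary", call. = FALSE)
    }
    cls_map <- tibble::tibble(
      drug_code = dictionary$drug_code,
      label = purrr::map_chr(dictionary$atc_path, function(p) {
        if (length(p) >= level) p[[level]] else NA_character_
      })
    ) |>
      dplyr::filter(!is.na(.data$label))
    out <- long |>
      dplyr::inner_join(cls_map, by = "drug_code") |>
      dplyr::distinct(.data$report_id, .data$label) |>
      dplyr::count(.data$label, name = "n")
  }
  out |>
    dplyr::mutate(pct = pct_of(.data$n, n_total)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$label) |>
    dplyr::select("label", "n", "pct")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(n, pct) {
    ifelse(is.na(pct), format(n), sprintf("%s (%.1f)", format(n), pct))
  }
  cat("Case cohort:", x$n_total, "reports\n")
  cat("Age (known n =", x$age$denominator[1], ")\n")
  for (i in seq_len(nrow(x$age))) {
    cat("  ", format(x$age$level[i], width = 10),
        fmt(x$age$n[i], x$age$pct[i]), "\n")
  }
  cat("Country (top", nrow(x$country), ")\n")
  for (i in seq_len(nrow(x$country))) {
    cat("  ", format(x$country$country[i], width = 10),
        fmt(x$country$n[i], x$country$pct[i]), "\n")
  }
  cat("Reporter\n")
  for (i in seq_len(nrow(x$reporter))) {
    cat("  ", format(x$reporter$level[i], width = 12),
        fmt(x$reporter$n[i], x$reporter$pct[i]), "\n")
  }
  cat("Serious:", fmt(x$seriousness$n[1], x$seriousness$pct[1]),
      "  Fatal:", fmt(x$seriousness$n[2], x$seriousness$pct[2]), "\n")
  if (x$tto$n_known > 0) {
    cat(sprintf("Time to onset: median %g (IQR %g-%g) days, n known %d\n",
                x$tto$median, x$tto$q1, x$tto$q3, x$tto$n_known))
  }
  cat("Co-reported terms (top", nrow(x$coreported), ")\n")
  for (i in seq_len(nrow(x$coreported))) {
    cat("  ", format(x$coreported$term[i], width = 28),
        fmt(x$coreported$n[i], x$coreported$pct[i]), "\n")
  }
  cat("Outcome (known n =", x$outcome$denominator[1], ")\n")
  for (i in seq_len(nrow(x$outcome))) {
    cat("  ", format(x$outcome$level[i], width = 24),
        fmt(x$outcome$n[i], x$outcome$pct[i]), "\n")
  }
  invisible(x)
}

#' Turn a cohort summary into a long tidy tibble
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A tibble `section`, `label`, `n`, `pct`, `denominator`.
#' @export
tidy.cohort_summary <- function(x, ...) {
  grab <- function(tbl, section, label_col) {
    tibble::tibble(section = section, label = tbl[[label_col]],
                   n = as.numeric(tbl$n), pct = tbl$pct,
                   denominator = as.numeric(tbl$denominator))
  }
  dplyr::bind_rows(
    tibble::tibble(section = "total", label = "reports",
                   n = as.numeric(x$n_total), pct = NA_real_,
                   denominator = NA_real_),
    grab(x$age, "age", "level"),
    grab(x$country, "country", "country"),
    grab(x$reporter, "reporter", "level"),
    grab(x$seriousness, "seriousness", "level"),
    tibble::tibble(section = "time_to_onset",
                   label = c("median", "q1", "q3"),
                   n = c(x$tto$median, x$tto$q1, x$tto$q3),
                   pct = NA_real_,
                   denominator = as.numeric(x$tto$n_known)),
    grab(x$coreported, "coreported_term", "term"),
    grab(x$outcome, "outcome", "level")
  )
}

#' @rdname tidy.cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    n_serious = x$seriousness$n[1],
    pct_serious = x$seriousness$pct[1],
    n_fatal = x$seriousness$n[2],
    pct_fatal = x$seriousness$pct[2],
    tto_median = x$tto$median,
    tto_n_known = x$tto$n_known
  )
}

#' Export a cohort summary
#'
#' Writes the two-column "characteristic, count (pct)" table that mirrors a
#' printed report-characteristics table and, optionally, a machine-readable
#' JSON variant with explicit denominators.
#'
#' @param x A `cohort_summary`.
#' @param path Output path for the delimited table.
#' @param json_path Optional path for the JSON variant.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(x, path, json_path = NULL) {
  long <- tidy.cohort_summary(x)
  flat <- tibble::tibble(
    characteristic = paste(long$section, long$label, sep = ": "),
    value = ifelse(is.na(long$pct), format(long$n, trim = TRUE),
                   sprintf("%s (%.1f)", format(long$n, trim = TRUE),
                           long$pct))
  )
  readr::write_csv(flat, path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(long, json_path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
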