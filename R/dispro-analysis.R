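#' Full disproportionality analysis of a report database
#'
#' End-to-end pipeline: select the case reports defined by `case_terms`,
#' build one 2x2 table per substance (and per class at `class_level`, when
#' given), compute reporting odds ratios and information components, flag
#' signals by the classical criteria and rank. This is the programmatic
#' twin of a signal-detection run against a spontaneous-reporting database.
#'
#' @inheritParams contingency_tables
#' @inheritParams dispro_stats
#' @param rank_by Ranking key passed to [rank_results()].
#' @return An object of class `dispro_analysis` with elements `results`
#'   (ranked tibble, all substances/classes, `is_signal` flagged),
#'   `n_db`, `n_cases`, `case_terms` and the parameters used. Use
#'   [tidy()][tidy.dispro_analysis()] for the results tibble,
#'   [glance()][tidy.dispro_analysis()] for the one-row run summary,
#'   [apply_signal_criteria()] to extract the signal subset, and
#'   [autoplot.dispro_analysis()] to visualise.
#' @examples
#' sim <- generate_reports(default_sim_config(n_reports = 2000))
#' fit <- dispro_analysis(sim$reports, "tubulointerstitial_nephritis")
#' head(tidy(fit))
#' glance(fit)
#' @export
dispro_analysis <- function(db, case_terms, dictionary = NULL,
                            class_level = NULL, alpha = 0.05,
                            ic_method = c("gamma", "bcpnn"),
                            min_reports = 30, ic_threshold = 0,
                            rank_by = c("n_reports", "ror")) {
  ic_method <- match.arg(ic_method)
  rank_by <- match.arg(rank_by)
  tables <- contingency_tables(db, case_terms, dictionary = dictionary,
                               class_level = class_level)
  results <- dispro_stats(tables, alpha = alpha, ic_method = ic_method,
                          min_reports = min_reports,
                          ic_threshold = ic_threshold)
  results <- rank_results(results, by = rank_by)
  structure(list(results = results,
                 n_db = nrow(db),
                 n_cases = results$a[1] + results$c[1],
                 case_terms = case_terms,
                 alpha = alpha, ic_method = ic_method,
                 min_reports = min_reports, ic_threshold = ic_threshold,
                 rank_by = rank_by),
            class = "dispro_analysis")
}

#' @export
print.dispro_analysis <- function(x, n = 10, ...) {
  cat("Disproportionality analysis\n")
  cat("  database:", x$n_db, "reports;  cases:", x$n_cases,
      sprintf("(%s)\n", paste(x$case_terms, collapse = ", ")))
  cat("  signals (IC025 >", x$ic_threshold, ", n >=", x$min_reports, "):",
      sum(x$results$is_signal), "of", nrow(x$results), "\n")
  top <- utils::head(x$results, n)
  cols <- intersect(c("label", "level", "n", "pct_of_cases", "ror",
                      "ror_low", "ror_high", "ic025", "is_signal"),
                    names(top))
  print(as.data.frame(top[, cols]), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy and glance methods for disproportionality analyses
#'
#' `tidy()` returns the per-drug/per-class results tibble; `glance()` a
#' one-row summary of the run.
#'
#' @param x A `dispro_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dispro_analysis <- function(x, ...) {
  x$results
}

#' @rdname tidy.dispro_analysis
#' @export
glance.dispro_analysis <- function(x, ...) {
  tibble::tibble(
    n_db = x$n_db,
    n_cases = x$n_cases,
    n_tested = nrow(x$results),
    n_signals = sum(x$results$is_signal),
    n_positive_ic025 = sum(x$results$ic025 > 0),
    alpha = x$alpha,
    ic_method = x$ic_method,
    min_reports = x$min_reports,
    ic_threshold = x$ic_threshold
  )
}
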