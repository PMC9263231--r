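#' Reporting odds ratio with Woolf confidence interval
#'
#' For a 2x2 report table (`a` exposed cases, `b` exposed non-cases, `c`
#' unexposed cases, `d` unexposed non-cases) the reporting odds ratio is
#' `ROR = (a d) / (b c)`, with the log-odds normal (Woolf) interval
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, the Haldane-Anscombe correction adds 0.5 to all four cells and the
#' result is flagged `corrected`. A drug mentioned on no report
#' (`a + b = 0`) or on every report (`c + d = 0`) has no estimable odds
#' ratio; such rows return `NA` with `estimable = FALSE`.
#'
#' @param a,b,c,d Cell counts (vectorised).
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return A tibble with columns `ror`, `ror_low`, `ror_high`, `corrected`,
#'   `estimable`.
#' @examples
#' ror_ci(30, 70, 100, 900) # ROR 3.86, 95% CI approximately (2.40, 6.20)
#' @export
ror_ci <- function(a, b, c, d, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  k <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), k); b <- rep_len(as.numeric(b), k)
  c <- rep_len(as.numeric(c), k); d <- rep_len(as.numeric(d), k)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  estimable <- (a + b) > 0 & (c + d) > 0
  corrected <- estimable & (a == 0 | b == 0 | c == 0 | d == 0)
  a2 <- a + 0.5 * corrected; b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected; d2 <- d + 0.5 * corrected
  z <- stats::qnorm(1 - alpha / 2)
  log_ror <- log(a2) + log(d2) - log(b2) - log(c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  out <- tibble::tibble(
    ror = exp(log_ror),
    ror_low = exp(log_ror - z * se),
    ror_high = exp(log_ror + z * se),
    corrected = corrected,
    estimable = estimable
  )
  out$ror[!estimable] <- NA_real_
  out$ror_low[!estimable] <- NA_real_
  out$ror_high[!estimable] <- NA_real_
  out
}

#' Expected exposed-case count under independence
#'
#' `E = (a + b)(a + c) / (a + b + c + d)`: the number of exposed case
#' reports expected if drug mention and case status were independent in the
#' database. This is the denominator of the observed-to-expected ratio
#' behind the information component.
#'
#' @inheritParams ror_ci
#' @return Numeric vector of expected counts.
#' @export
expected_count <- function(a, b, c, d) {
  n <- a + b + c + d
  if (any(n <= 0)) stop("table must contain at least one report", call. = FALSE)
  (a + b) * (a + c) / n
}

#' Shrinkage information component with lower credibility bound (IC025)
#'
#' The default (`method = "gamma"`) is the shrinkage observed-to-expected
#' formulation: `IC = log2((a + 0.5) / (E + 0.5))` with the credibility
#' interval taken from a Gamma posterior with shape `a + 0.5` and rate
#' `E + 0.5`; `IC025 = log2(q)` where `q` is that posterior's 2.5%
#' quantile. The 0.5 shrinkage pulls small-count pairs toward IC = 0, so
#' every cell configuration is estimable without continuity correction.
#' `method = "bcpnn"` gives the legacy Bayesian confidence propagation
#' neural network normal approximation (Dirichlet/Beta priors on the joint
#' and marginal reporting probabilities), retained for comparison with
#' older analyses.
#'
#' @param a Observed exposed-case count(s).
#' @param e Expected count(s) under independence, from [expected_count()].
#' @param alpha Credibility level (default 0.05: IC025/IC975 bounds).
#' @param method `"gamma"` (default) or `"bcpnn"`.
#' @param n,n_exposed,n_cases Database size, exposed margin `a + b` and
#'   case margin `a + c`; required by `method = "bcpnn"` only.
#' @return A tibble with columns `ic` and `ic025` (bits).
#' @examples
#' information_component(30, 3) # IC about 3.12 bits
#' @export
information_component <- function(a, e, alpha = 0.05,
                                  method = c("gamma", "bcpnn"),
                                  n = NULL, n_exposed = NULL, n_cases = NULL) {
  method <- match.arg(method)
  stopifnot(all(a >= 0), all(e >= 0), alpha > 0, alpha < 1)
  if (method == "gamma") {
    ic <- log2((a + 0.5) / (e + 0.5))
    ic025 <- log2(stats::qgamma(alpha / 2, shape = a + 0.5, rate = e + 0.5))
    return(tibble::tibble(ic = ic, ic025 = ic025))
  }
  if (is.null(n) || is.null(n_exposed) || is.null(n_cases)) {
    stop("method = \"bcpnn\" needs n, n_exposed and n_cases", call. = FALSE)
  }
  ic_bcpnn(a, n, n_exposed, n_cases, alpha)
}

# Legacy BCPNN normal approximation (Bate et al. 1998 priors:
# gamma11 = 1, alpha1 = beta1 = 1, alpha = beta = 2).
ic_bcpnn <- function(a, n, n1., n.1, alpha) {
  g11 <- 1; a1 <- 1; b1 <- 1; aa <- 2; bb <- 2
  gg <- g11 * (n + aa) * (n + bb) / ((n1. + a1) * (n.1 + b1))
  ic <- log2((a + g11) * (n + aa) * (n + bb) /
               ((n + gg) * (n1. + a1) * (n.1 + b1)))
  v <- (1 / log(2)^2) * (
    (n - a + gg - g11) / ((a + g11) * (1 + n + gg)) +
      (n - n1. + aa - a1) / ((n1. + a1) * (1 + n + aa)) +
      (n - n.1 + bb - b1) / ((n.1 + b1) * (1 + n + bb))
  )
  z <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(ic = ic, ic025 = ic - z * sqrt(v))
}

#' Disproportionality statistics for a set of contingency tables
#'
#' Augments the tables from [contingency_tables()] with the report count
#' `n` (= `a`), the percentage of case reports mentioning the drug, the
#' reporting odds ratio with its Woolf interval, the expected count, the
#' shrinkage information component with IC025, and the classical signal
#' flag (`ic025 > ic_threshold` and `n >= min_reports`).
#'
#' @param tables Tibble with columns `label`, `a`, `b`, `c`, `d` (extra
#'   columns are carried through).
#' @param alpha Significance / credibility level (default 0.05).
#' @param ic_method `"gamma"` (default) or `"bcpnn"`; see
#'   [information_component()].
#' @param min_reports,ic_threshold Signal criteria applied to the `is_signal`
#'   flag (defaults: at least 30 reports and IC025 > 0).
#' @return A tibble with columns `label`, (any carried columns,) `n`,
#'   `pct_of_cases`, `ror`, `ror_low`, `ror_high`, `corrected`,
#'   `estimable`, `e`, `ic`, `ic025`, `is_signal`.
#' @export
dispro_stats <- function(tables, alpha = 0.05,
                         ic_method = c("gamma", "bcpnn"),
                         min_reports = 30, ic_threshold = 0) {
  ic_method <- match.arg(ic_method)
  stopifnot(all(c("label", "a", "b", "c", "d") %in% names(tables)))
  t <- tibble::as_tibble(tables)
  n_tot <- t$a + t$b + t$c + t$d
  r <- ror_ci(t$a, t$b, t$c, t$d, alpha = alpha)
  e <- expected_count(t$a, t$b, t$c, t$d)
  ic <- information_component(t$a, e, alpha = alpha, method = ic_method,
                              n = n_tot, n_exposed = t$a + t$b,
                              n_cases = t$a + t$c)
  out <- dplyr::bind_cols(
    t,
    tibble::tibble(n = t$a, pct_of_cases = pct_of(t$a, t$a + t$c), e = e),
    r, ic
  )
  flag_signals(out, min_reports = min_reports, ic_threshold = ic_threshold)
}

flag_signals <- function(results, min_reports = 30, ic_threshold = 0) {
  results$is_signal <- results$ic025 > ic_threshold &
    results$n >= min_reports
  results
}

#' Apply the classical signal-screening criteria
#'
#' Keeps the results with `ic025 > ic_threshold` and at least `min_reports`
#' exposed case reports (the IC025 > 0, n >= 30 screening rule), after
#' refreshing the `is_signal` flag on every input row. With
#' `filter = FALSE` all rows are returned with the flag updated.
#'
#' @param results Tibble from [dispro_stats()].
#' @param min_reports Minimum exposed-case report count (default 30).
#' @param ic_threshold IC025 threshold in bits (default 0).
#' @param filter Return only the signals (default) or all rows.
#' @return A tibble.
#' @export
apply_signal_criteria <- function(results, min_reports = 30,
                                  ic_threshold = 0, filter = TRUE) {
  stopifnot(all(c("n", "ic025") %in% names(results)))
  results <- flag_signals(results, min_reports, ic_threshold)
  if (filter) results[results$is_signal, ] else results
}

#' Rank disproportionality results
#'
#' Stable descending sort by the chosen key, ties broken alphabetically by
#' label (so rankings are reproducible across runs).
#'
#' @param results Tibble from [dispro_stats()].
#' @param by `"n_reports"` (the exposed-case count) or `"ror"`.
#' @return The ranked tibble.
#' @export
rank_results <- function(results, by = c("n_reports", "ror")) {
  by <- match.arg(by)
  key <- if (by == "n_reports") results$n else results$ror
  results[order(-key, results$label, method = "radix"), ]
}

#' Export disproportionality results as a delimited table
#'
#' Writes the machine-readable results table (`label, n, pct_of_cases, ror,
#' ror_low, ror_high, ic, ic025, is_signal` plus any carried columns,
#' list-columns dropped).
#'
#' @param results Tibble from [dispro_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dispro_results <- function(results, path) {
  keep <- names(results)[!purrr::map_lgl(results, is.list)]
  readr::write_csv(results[, keep], path, progress = FALSE)
  invisible(path)
}
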