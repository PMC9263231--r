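#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a disproportionality analysis
#'
#' Scatter of the lower IC credibility bound (IC025) against the reporting
#' odds ratio (log scale), point size by the exposed-case report count and
#' colour by signal status, with the classical IC025 = 0 threshold drawn.
#' Rows without an estimable ROR are dropped.
#'
#' @param object A `dispro_analysis` object.
#' @param label_signals Label the flagged signals with their drug names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dispro_analysis <- function(object, label_signals = TRUE, ...) {
  df <- object$results
  df <- df[df$estimable, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$ic025)) +
    ggplot2::geom_hline(yintercept = object$ic_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n,
                                     colour = .data$is_signal),
                        alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "reporting odds ratio (log scale)",
                  y = "IC025 (bits)", size = "case reports",
                  colour = "signal") +
    ggplot2::theme_minimal()
  if (label_signals && any(df$is_signal)) {
    p <- p + ggplot2::geom_text(
      data = df[df$is_signal, ],
      ggplot2::aes(label = .data$label),
      size = 2.8, vjust = -0.8, check_overlap = TRUE
    )
  }
  p
}

#' Forest plot of reporting odds ratios
#'
#' Point estimates and 95% intervals for the top-ranked drugs or classes of
#' an analysis, ordered as ranked.
#'
#' @param x A `dispro_analysis` object or a [dispro_stats()] tibble.
#' @param top How many rows to display.
#' @return A ggplot object.
#' @export
plot_ror_forest <- function(x, top = 15) {
  df <- if (inherits(x, "dispro_analysis")) x$results else x
  df <- df[df$estimable, ]
  df <- utils::head(df, top)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_low,
                                         xmax = .data$ror_high),
                            height = 0.2, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_signal), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "#b2182b"),
                                 guide = "none") +
    ggplot2::labs(x = "reporting odds ratio (95% CI, log scale)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cohort summary
#'
#' Bar panels of the age-band, reporter and outcome distributions of a
#' [summarize_cohort()] result.
#'
#' @param object A `cohort_summary` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  long <- tidy(object)
  long <- long[long$section %in% c("age", "reporter", "outcome"), ]
  long$label <- factor(long$label, levels = unique(long$label))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(ggplot2::vars(.data$section), scales = "free") +
    ggplot2::labs(x = NULL, y = "reports") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Histogram of time to onset
#'
#' Log-scaled histogram of the known time-to-onset values of a cohort, with
#' the median marked — the typical display for the right-skewed onset
#' distribution of drug-induced reactions.
#'
#' @param cases A report-set tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_time_to_onset <- function(cases, bins = 40) {
  tto <- cases$time_to_onset_days
  df <- tibble::tibble(tto = tto[!is.na(tto)])
  med <- stats::median(df$tto)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tto + 1)) +
    ggplot2::geom_histogram(bins = bins, fill = "#2166ac",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = med + 1, colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time to onset + 1 (days, log scale)",
                  y = "reports") +
    ggplot2::theme_minimal()
}
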