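# ggplot2 views of the main result types.

#' Plot a power spectrum
#'
#' One line per channel of the per-channel power (dB) against frequency,
#' restricted to `xlim`.
#'
#' @param object An `eeg_spectrum`.
#' @param xlim Frequency range to display in Hz.
#' @param ... Unused.
#'
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eeg_spectrum <- function(object, xlim = c(1, 40), ...) {
  df <- as_tibble(object) %>%
    filter(.data$freq >= xlim[1], .data$freq <= xlim[2])
  ggplot(df, aes(x = .data$freq, y = .data$power_db,
                 colour = .data$channel)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "power (dB)",
         title = if (is.na(object$condition)) NULL else object$condition,
         colour = "channel") +
    theme_minimal()
}

#' Plot a normative model
#'
#' The normative mean curve with its central band over the training age
#' range, the training subjects, and optionally scored subjects coloured
#' by group.
#'
#' @param object A `normative_model`.
#' @param scored Optional scored tibble from [score_normative()] with
#'   columns `age_months` (or `age`), `value`-like metric column, and
#'   `group`.
#' @param level Band coverage (default 0.95).
#' @param ... Unused.
#'
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.normative_model <- function(object, scored = NULL, level = 0.95,
                                     ...) {
  band <- tidy(object)
  p <- ggplot(band, aes(x = .data$age)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "steelblue", alpha = 0.2) +
    geom_line(aes(y = .data$mean), colour = "steelblue") +
    geom_point(data = tibble(age = object$train_ages,
                             value = object$train_values),
               aes(y = .data$value), alpha = 0.5) +
    labs(x = "age (months)", y = object$metric) +
    theme_minimal()
  if (!is.null(scored)) {
    agecol <- if ("age_months" %in% names(scored)) "age_months" else "age"
    p <- p + geom_point(
      data = scored,
      aes(x = .data[[agecol]], y = .data$value, colour = .data$group),
      inherit.aes = FALSE)
  }
  p
}

#' Histogram of normative deviation scores by group
#'
#' @param scores Tibble from [run_pipeline()]'s `scores` (or
#'   [score_normative()] output with a `metric` column added).
#' @param outlier_z Threshold drawn as vertical lines.
#'
#' @return A ggplot.
#' @export
plot_score_histogram <- function(scores, outlier_z = 1.96) {
  ggplot(filter(scores, is.finite(.data$z)),
         aes(x = .data$z, fill = .data$group)) +
    geom_histogram(position = "identity", alpha = 0.5, bins = 25) +
    geom_vline(xintercept = c(-outlier_z, outlier_z), linetype = 2) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "normative deviation score z", y = "subjects") +
    theme_minimal()
}
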