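# ggplot2 presentation methods for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_abline
#'   geom_boxplot geom_histogram facet_wrap labs scale_x_reverse
#'   scale_x_log10 theme_minimal
NULL

#' Plot diversity and turnover-rate series
#'
#' One panel each for range-through diversity and the per-capita
#' origination/extinction rates across bins (old bins left).
#'
#' @param object a `diversity_counts` tibble from [foote_rates()].
#' @param ... unused.
#' @export
autoplot.diversity_counts <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("bin", "diversity", "p_rate", "q_rate")],
    c("diversity", "p_rate", "q_rate"),
    names_to = "series", values_to = "value")
  long$series <- factor(long$series, c("diversity", "p_rate", "q_rate"),
                        c("range-through diversity",
                          "origination rate (per capita)",
                          "extinction rate (per capita)"))
  ggplot(long, aes(x = .data$bin, y = .data$value)) +
    geom_line(na.rm = TRUE) + geom_point(size = 0.8, na.rm = TRUE) +
    facet_wrap(~series, ncol = 1, scales = "free_y") +
    labs(x = "time bin (old to young)", y = NULL) +
    theme_minimal()
}

#' Reliability diagram for a calibration table
#'
#' Empirical accuracy per probability bin against the diagonal of perfect
#' calibration.
#'
#' @param object a `calibration_table`.
#' @param ... unused.
#' @export
autoplot.calibration_table <- function(object, ...) {
  object$centre <- (object$bin_lo + object$bin_hi) / 2
  ggplot(object, aes(x = .data$centre, y = .data$empirical_accuracy)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_col(width = 0.08, fill = "steelblue", na.rm = TRUE) +
    labs(x = "predicted probability (bin centre)", y = "empirical accuracy") +
    theme_minimal()
}

#' Training-size curve plot
#'
#' Accuracy of the extracted diversity history (detrended Spearman rho
#' against gold) as the seed knowledge base grows.
#'
#' @param object a `training_curve` tibble from [training_size_curve()].
#' @param ... unused.
#' @export
autoplot.training_curve <- function(object, ...) {
  ok <- object[object$status == "ok", ]
  ggplot(ok, aes(x = factor(.data$fraction), y = .data$rho)) +
    geom_boxplot(outlier.size = 0.8) +
    labs(x = "seed-KB fraction", y = "Spearman rho (first differences)") +
    theme_minimal()
}

#' Histogram of genus range offsets
#'
#' @param object a `range_offsets` tibble.
#' @param ... unused.
#' @export
autoplot.range_offsets <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("first_offset", "last_offset"),
                              names_to = "which", values_to = "offset")
  ggplot(long, aes(x = .data$offset)) +
    geom_histogram(bins = 30, fill = "steelblue") +
    facet_wrap(~which, ncol = 1) +
    labs(x = "offset (Myr)", y = "genera") +
    theme_minimal()
}
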