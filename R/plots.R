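#' Plots
#'
#' ggplot2 figures for calibration curves, weight distributions and balance
#' diagnostics. Every `plot_*()` function has a matching `autoplot()` method.
#'
#' @name plots
NULL

#' Calibration plot
#'
#' Loess calibration curve against the ideal diagonal, annotated with the
#' AUROC when the input is a full [assess_model()] result.
#'
#' @param x A `"model_assessment"` or `"calibration_curve"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_calibration <- function(x, ...) {
  if (inherits(x, "model_assessment")) {
    curve <- x$curve
    label <- sprintf("AUC: %.2f (95%% CI: %.2f-%.2f)",
                     x$discrimination$auroc, x$discrimination$ci_low,
                     x$discrimination$ci_high)
  } else {
    curve <- x
    label <- NULL
  }
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "#2166ac",
                       linewidth = 0.8, na.rm = TRUE) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted probability of continuing",
                  y = "Observed proportion (loess)") +
    ggplot2::theme_minimal()
  if (!is.null(label)) {
    p <- p + ggplot2::annotate("text", x = 0.05, y = 0.95, hjust = 0,
                               label = label, size = 3.5)
  }
  p
}

#' @export
autoplot.model_assessment <- function(object, ...) plot_calibration(object, ...)

#' @export
autoplot.calibration_curve <- function(object, ...) plot_calibration(object, ...)

#' Weight distribution plot
#'
#' Histogram of the responders' stabilized weights, before and after
#' truncation when available.
#'
#' @param ws A `"weight_set"`.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_weights <- function(ws, bins = 60) {
  resp <- as_tibble(ws) |> filter(.data$participation == 1L)
  long <- resp |>
    tidyr::pivot_longer(dplyr::any_of(c("sw", "sw_trunc")),
                        names_to = "stage", values_to = "weight") |>
    mutate(stage = dplyr::recode(.data$stage, sw = "stabilized",
                                 sw_trunc = "truncated"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "#2166ac", colour = NA) +
    ggplot2::facet_wrap(~stage, ncol = 1) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Stabilized weight (responders)", y = "Count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.weight_set <- function(object, ...) plot_weights(object, ...)

#' Balance dot plot
#'
#' Absolute standardized differences by variable, one point per weighting
#' scheme, with the conventional 10% reference line.
#'
#' @param x A `"balance_report"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_balance <- function(x, ...) {
  long <- tidy.balance_report(x)
  ord <- as_tibble(x) |> arrange(.data$unweighted) |> pull("variable")
  long$variable <- factor(long$variable, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$abs_std_diff,
                                     y = .data$variable,
                                     colour = .data$scheme)) +
    ggplot2::geom_vline(xintercept = attr(x, "threshold") %||% 10,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Absolute standardized difference (%)", y = NULL,
                  colour = "Scheme") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.balance_report <- function(object, ...) plot_balance(object, ...)

#' Multiwave balance dot plot
#'
#' Weighted absolute standardized differences by variable, coloured by wave.
#'
#' @param x A `"multiwave_balance"`.
#' @param scheme Scheme to display (default `"weighted"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_multiwave_balance <- function(x, scheme = "weighted", ...) {
  d <- as_tibble(x) |> filter(.data$scheme == !!scheme)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$abs_std_diff, y = .data$variable,
                                  colour = .data$wave)) +
    ggplot2::geom_vline(xintercept = 10, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Absolute standardized difference (%)", y = NULL,
                  colour = "Wave") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.multiwave_balance <- function(object, ...) {
  plot_multiwave_balance(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
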