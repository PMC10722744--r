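#' Broom-style tidiers
#'
#' `tidy()` returns per-term/per-row tibbles, `glance()` one-row model-level
#' summaries, for the package's fitted objects.
#'
#' @name tidiers
NULL

#' @describeIn tidiers Coefficient table of a participation model
#'   (`term`, `variable`, `level`, `estimate`, `std_error`), intercept first.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.participation_model <- function(x, ...) {
  bind_rows(
    tibble(term = "(Intercept)", variable = NA_character_,
           level = NA_character_, estimate = x$intercept,
           std_error = NA_real_),
    x$coefficients |>
      dplyr::rename(term = "column", std_error = dplyr::any_of("std_error")) |>
      select("term", "variable", "level", "estimate", "std_error")
  )
}

#' @describeIn tidiers One-row summary of a participation model.
#' @export
glance.participation_model <- function(x, ...) {
  tibble(method = x$method, wave = x$wave,
         n_variables = length(x$variables),
         n_coefficients = nrow(x$coefficients),
         ridge_stabilized = x$ridge)
}

#' @describeIn tidiers Penalized coefficients of a LASSO screen.
#' @export
tidy.cv_lasso_fit <- function(x, ...) {
  x$coefficients |> dplyr::rename(term = "column")
}

#' @describeIn tidiers One-row summary of a LASSO screen.
#' @export
glance.cv_lasso_fit <- function(x, ...) {
  tibble(lambda = x$lambda, wave = x$wave,
         n_nonzero = sum(x$coefficients$coefficient != 0),
         n_columns = nrow(x$coefficients))
}

#' @describeIn tidiers Forward-selection walk of a theme
#'   (`step`, `variable`, `auroc`, `p`, `action`).
#' @export
tidy.selection_trace <- function(x, ...) x$trace

#' @describeIn tidiers Weight table as a plain tibble.
#' @export
tidy.weight_set <- function(x, ...) as_tibble(x)

#' @describeIn tidiers One-row weight summary (see [weight_summary()]).
#' @export
glance.weight_set <- function(x, ...) weight_summary(x)

#' @describeIn tidiers Long-format balance table
#'   (`variable`, `scheme`, `abs_std_diff`).
#' @export
tidy.balance_report <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-"variable", names_to = "scheme",
                        values_to = "abs_std_diff")
}

#' @describeIn tidiers Per-scheme max/mean/flag-count summary of a balance
#'   report.
#' @export
glance.balance_report <- function(x, ...) {
  attr(x, "summary") |> mutate(wave = attr(x, "wave") %||% NA_character_)
}

#' @describeIn tidiers Multiwave balance in long format (already tidy).
#' @export
tidy.multiwave_balance <- function(x, ...) as_tibble(x)

#' @describeIn tidiers Per-wave, per-scheme summary of multiwave balance.
#' @export
glance.multiwave_balance <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$wave, .data$scheme) |>
    summarise(max_abs_d = max(.data$abs_std_diff),
              mean_abs_d = mean(.data$abs_std_diff), .groups = "drop")
}

#' @describeIn tidiers One-row discrimination + calibration summary of a
#'   model assessment.
#' @export
glance.model_assessment <- function(x, ...) {
  tibble(wave = x$wave,
         auroc = x$discrimination$auroc,
         auroc_ci_low = x$discrimination$ci_low,
         auroc_ci_high = x$discrimination$ci_high,
         hl_statistic = x$hosmer_lemeshow$statistic,
         hl_df = x$hosmer_lemeshow$df,
         hl_p = x$hosmer_lemeshow$p,
         mean_predicted = x$mean_calibration$mean_predicted,
         observed_rate = x$mean_calibration$observed_rate)
}
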