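#' Inverse-probability-of-participation weights
#'
#' Predicted continuation probabilities from a participation model are turned
#' into stabilized weights `sw = p_bar / p_hat` (`p_bar` the observed marginal
#' continuation proportion), computed for *every* baseline participant;
#' analyses consume the responder subset, where the weights average
#' approximately 1 (exactly 1 under a saturated model). Extreme weights are
#' clamped to empirical percentile bounds (default 0.5th/99.5th, linear
#' interpolation between order statistics).
#'
#' @name weighting
NULL

#' Predicted continuation probabilities
#'
#' Applies the inverse logistic link to the model's linear predictor for all
#' baseline participants. Categorical cells carrying a level the model never
#' saw are mapped to the reference level with a warning (this happens when a
#' model is re-fit at a later wave on slightly different data).
#'
#' @param model A `"participation_model"`.
#' @param data Prepared cohort data (missing-category recode applied).
#' @return Tibble `participant_id`, `p_hat`.
#' @export
predict_probabilities <- function(model, data) {
  lp <- rep(model$intercept, nrow(data))
  for (v in model$variables) {
    x <- data[[v]]
    if (is.null(x)) {
      abort(paste0("Model variable '", v, "' not present in data."),
            class = "aw_schema_error")
    }
    rows <- model$coefficients[model$coefficients$variable == v, ]
    if (nrow(rows) > 0 && all(is.na(rows$level))) {
      if (anyNA(x)) abort(paste0("Variable '", v, "' has missing values; ",
                                 "prepare the cohort first."),
                          class = "aw_validation_error")
      lp <- lp + rows$estimate[1] * as.numeric(x)
    } else if (nrow(rows) > 0) {
      known <- c(model$levels[[v]][1], rows$level)
      unseen <- !is.na(x) & !(x %in% known)
      if (any(unseen)) {
        warn(paste0("Variable '", v, "' has level(s) unseen at fit time (",
                    paste(unique(x[unseen]), collapse = ", "),
                    "); mapped to the reference level."),
             class = "aw_unseen_level_warning")
      }
      if (anyNA(x)) abort(paste0("Variable '", v, "' has missing values; ",
                                 "prepare the cohort first."),
                          class = "aw_validation_error")
      for (i in seq_len(nrow(rows))) {
        lp <- lp + rows$estimate[i] * (x == rows$level[i])
      }
    }
  }
  tibble(participant_id = data$participant_id, p_hat = plogis(lp))
}

#' Stabilized weights
#'
#' `sw_i = p_bar / p_hat_i` with `p_bar` the observed continuation
#' proportion. Probabilities of exactly 0 (infinite weight) are an error —
#' they indicate a separated fit; use the ridge-stabilized fallback.
#' Probabilities of exactly 1 are admitted (they arise under saturated
#' models and give finite weights).
#'
#' @param p_hat Predicted continuation probabilities, or the tibble returned
#'   by [predict_probabilities()].
#' @param participation 0/1 wave participation indicator.
#' @param wave Optional wave label recorded on the result.
#' @param participant_id Optional ids (taken from `p_hat` when it is a
#'   tibble).
#' @return Tibble of class `"weight_set"`: `participant_id`, `participation`,
#'   `p_hat`, `sw`; attributes `p_bar` and `wave`.
#' @export
stabilized_weights <- function(p_hat, participation, wave = NULL,
                               participant_id = NULL) {
  if (is.data.frame(p_hat)) {
    participant_id <- participant_id %||% p_hat$participant_id
    p_hat <- p_hat$p_hat
  }
  participation <- check_binary_labels(participation)
  if (length(p_hat) != length(participation)) {
    abort("p_hat and participation must have the same length.",
          class = "aw_argument_error")
  }
  if (any(p_hat <= 0)) {
    abort(paste0("Predicted probabilities of 0 give infinite weights; ",
                 "re-fit with the ridge-stabilized fallback."),
          class = "aw_numeric_error")
  }
  if (any(p_hat > 1)) {
    abort("Predicted probabilities must not exceed 1.", class = "aw_numeric_error")
  }
  p_bar <- mean(participation)
  out <- tibble(
    participant_id = participant_id %||% sprintf("P%05d", seq_along(p_hat)),
    participation = participation,
    p_hat = p_hat,
    sw = p_bar / p_hat
  )
  attr(out, "p_bar") <- p_bar
  attr(out, "wave") <- wave
  class(out) <- c("weight_set", class(out))
  out
}

# Preserve weight_set attributes across dplyr-style column additions.
ws_restore <- function(out, ws) {
  attr(out, "p_bar") <- attr(ws, "p_bar")
  attr(out, "wave") <- attr(ws, "wave")
  for (a in c("trunc_low", "trunc_high", "trunc_pct")) {
    if (!is.null(attr(ws, a))) attr(out, a) <- attr(ws, a)
  }
  if (!inherits(out, "weight_set")) class(out) <- c("weight_set", class(out))
  out
}

#' Truncate weights at empirical percentiles
#'
#' Bounds are the `low_pct` and `high_pct` empirical percentiles of the
#' weights (linear interpolation between order statistics, quantile type 7);
#' weights strictly outside the bounds are set to the bound. Setting
#' `low_pct = 0` gives one-sided (upper-only) truncation. Re-truncating at
#' the same percentiles leaves already-truncated weights unchanged except for
#' the (narrower) bounds of the clamped distribution.
#'
#' The altered-weight count depends on the empirical-quantile convention, so
#' it is configurable: `qtype = 7` (default) interpolates linearly between
#' order statistics; `qtype = 1` (inverse empirical CDF) makes re-truncation
#' exactly idempotent because the bound of an already-clamped vector is the
#' bound itself. Under the default, re-truncation is idempotent up to the
#' interpolation step below the clamped mass.
#'
#' @param ws A `"weight_set"` from [stabilized_weights()].
#' @param low_pct,high_pct Percentiles in `[0, 100]`, `low_pct < high_pct`
#'   (defaults 0.5 and 99.5).
#' @param qtype Quantile type passed to [stats::quantile()] (default 7).
#' @return The weight set with columns `sw_trunc` and `altered` added;
#'   attributes `trunc_low`, `trunc_high`, `trunc_pct`.
#' @export
truncate_weights <- function(ws, low_pct = 0.5, high_pct = 99.5, qtype = 7) {
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct) {
    abort("Truncation percentiles must satisfy 0 <= low < high <= 100.",
          class = "aw_argument_error")
  }
  w <- ws$sw
  bounds <- quantile(w, probs = c(low_pct, high_pct) / 100, type = qtype,
                     names = FALSE)
  out <- ws |>
    mutate(sw_trunc = pmin(pmax(.data$sw, bounds[1]), bounds[2]),
           altered = .data$sw < bounds[1] | .data$sw > bounds[2])
  out <- ws_restore(out, ws)
  attr(out, "trunc_low") <- bounds[1]
  attr(out, "trunc_high") <- bounds[2]
  attr(out, "trunc_pct") <- c(low = low_pct, high = high_pct)
  out
}

#' Summarise a weight set
#'
#' Mean, SD, min and max of the stabilized weights over the responders (the
#' analysis-facing subset), before and after truncation, plus the number of
#' altered weights over all participants.
#'
#' @param ws A `"weight_set"`.
#' @return One-row tibble.
#' @export
weight_summary <- function(ws) {
  resp <- ws[ws$participation == 1L, ]
  out <- tibble(
    wave = attr(ws, "wave") %||% NA_character_,
    p_bar = attr(ws, "p_bar"),
    n = nrow(ws),
    n_responders = nrow(resp),
    mean_sw = mean(resp$sw), sd_sw = sd(resp$sw),
    min_sw = min(resp$sw), max_sw = max(resp$sw)
  )
  if ("sw_trunc" %in% names(ws)) {
    out$mean_sw_trunc <- mean(resp$sw_trunc)
    out$sd_sw_trunc <- sd(resp$sw_trunc)
    out$min_sw_trunc <- min(resp$sw_trunc)
    out$max_sw_trunc <- max(resp$sw_trunc)
    out$n_altered <- sum(ws$altered)
  }
  out
}

#' Predicted probabilities, stabilized and truncated weights in one step
#'
#' @param model A `"participation_model"`.
#' @param data Prepared cohort data containing the model's wave indicator.
#' @param low_pct,high_pct Truncation percentiles (see [truncate_weights()]).
#' @return A truncated `"weight_set"`.
#' @export
compute_weights <- function(model, data, low_pct = 0.5, high_pct = 99.5) {
  p <- predict_probabilities(model, data)
  ws <- stabilized_weights(p, data[[wave_column(model$wave)]],
                           wave = model$wave)
  truncate_weights(ws, low_pct = low_pct, high_pct = high_pct)
}

#' Re-fit a selected variable set for a later wave
#'
#' The variable set chosen at the first assessed wave is kept; coefficients
#' are freshly estimated (unpenalized logistic regression) against the new
#' wave's participation indicator and the full weight pipeline re-run.
#'
#' @param model A `"participation_model"` (or a character vector of variable
#'   names).
#' @param data,dict Prepared cohort data and dictionary.
#' @param wave Wave label to re-fit for.
#' @param low_pct,high_pct Truncation percentiles.
#' @return A list: `model` (re-fitted), `weights` (truncated
#'   `"weight_set"`).
#' @export
refit_for_wave <- function(model, data, dict, wave, low_pct = 0.5,
                           high_pct = 99.5) {
  variables <- if (inherits(model, "participation_model")) model$variables else model
  method <- if (inherits(model, "participation_model")) model$method else "refit"
  refit <- fit_logistic_model(data, dict, variables, wave, method = method)
  list(model = refit,
       weights = compute_weights(refit, data, low_pct = low_pct,
                                 high_pct = high_pct))
}
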