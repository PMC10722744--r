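#' Standardized-difference balance diagnostics
#'
#' Weight performance is judged by absolute standardized differences of
#' baseline characteristics between continuers and drop-outs, with and
#' without weights, against the conventional 10% negligibility threshold.
#' For a continuous variable `d = (m1 - m0) / sqrt((s1^2 + s0^2) / 2)`; a
#' categorical variable is summarised by the maximum over its level-wise
#' dichotomous differences. All values are reported as `|d| x 100` (percent).
#'
#' In the default weighted comparison, continuers carry their truncated
#' stabilized weights `p_bar / p_hat` and drop-outs the complementary inverse
#' weights `(1 - p_bar) / (1 - p_hat)`, so both groups are reweighted toward
#' the full baseline distribution and a correctly specified model drives the
#' difference to zero. Comparisons use complete cases per variable.
#'
#' @name balance
NULL

weighted_moments <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  sw2 <- sum(w^2)
  if (sw^2 - sw2 <= 0) return(list(mean = m, var = 0))
  v <- sw / (sw^2 - sw2) * sum(w * (x - m)^2)
  list(mean = m, var = v)
}

std_diff_core <- function(x1, w1, x0, w0) {
  g1 <- weighted_moments(x1, w1)
  g0 <- weighted_moments(x0, w0)
  denom <- sqrt((g1$var + g0$var) / 2)
  if (denom == 0) {
    if (isTRUE(all.equal(g1$mean, g0$mean))) return(0)
    abort("Zero pooled variance with unequal group means; standardized difference undefined.",
          class = "aw_numeric_error")
  }
  (g1$mean - g0$mean) / denom
}

#' Standardized difference for a continuous variable
#'
#' @param x Numeric values (missing values are dropped as incomplete cases).
#' @param group 0/1: 1 = continuers, 0 = drop-outs.
#' @param weights Optional per-observation weights (default 1).
#' @return `|d| x 100` (percent).
#' @export
standardized_difference_continuous <- function(x, group, weights = NULL) {
  weights <- weights %||% rep(1, length(x))
  keep <- !is.na(x)
  x <- x[keep]; group <- group[keep]; weights <- weights[keep]
  if (!all(group %in% c(0, 1)) || length(unique(group)) < 2) {
    abort("group must contain both continuers (1) and drop-outs (0).",
          class = "aw_argument_error")
  }
  100 * abs(std_diff_core(x[group == 1], weights[group == 1],
                          x[group == 0], weights[group == 0]))
}

#' Standardized difference for a categorical variable
#'
#' Each realised level is treated as a dichotomy,
#' `d_l = (p1_l - p0_l) / sqrt((p1_l (1 - p1_l) + p0_l (1 - p0_l)) / 2)`,
#' and the variable-level difference is the maximum `|d_l|`. Levels absent
#' from both groups are skipped.
#'
#' @inheritParams standardized_difference_continuous
#' @param x Character/factor values.
#' @return `|d| x 100` (percent).
#' @export
standardized_difference_categorical <- function(x, group, weights = NULL) {
  weights <- weights %||% rep(1, length(x))
  keep <- !is.na(x)
  x <- as.character(x[keep]); group <- group[keep]; weights <- weights[keep]
  if (!all(group %in% c(0, 1)) || length(unique(group)) < 2) {
    abort("group must contain both continuers (1) and drop-outs (0).",
          class = "aw_argument_error")
  }
  levels <- unique(x)
  d <- 0
  for (l in levels) {
    ind <- as.numeric(x == l)
    p1 <- weighted.mean(ind[group == 1], weights[group == 1])
    p0 <- weighted.mean(ind[group == 0], weights[group == 0])
    denom <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    dl <- if (denom == 0) {
      if (isTRUE(all.equal(p1, p0))) 0
      else abort("Zero pooled variance with unequal level proportions.",
                 class = "aw_numeric_error")
    } else (p1 - p0) / denom
    d <- max(d, abs(dl))
  }
  100 * d
}

# Per-observation weight vector implementing the balance comparison scheme.
balance_weights <- function(ws, data, dropout_weighting = "inverse",
                            use_truncated = TRUE) {
  idx <- match(data$participant_id, ws$participant_id)
  if (anyNA(idx)) {
    abort("Weight set does not cover every participant.", class = "aw_schema_error")
  }
  sw <- if (use_truncated && "sw_trunc" %in% names(ws)) ws$sw_trunc else ws$sw
  p_bar <- attr(ws, "p_bar")
  w <- sw[idx]
  drop_idx <- ws$participation[idx] == 0L
  if (dropout_weighting == "inverse") {
    p_hat <- ws$p_hat[idx]
    if (any(p_hat[drop_idx] >= 1)) {
      abort("A drop-out has predicted probability 1; inverse drop-out weights undefined.",
            class = "aw_numeric_error")
    }
    w[drop_idx] <- (1 - p_bar) / (1 - p_hat[drop_idx])
  } else {
    w[drop_idx] <- 1
  }
  w
}

#' Balance table for one wave
#'
#' Absolute standardized differences between continuers and drop-outs for
#' the demographic variable panel, unweighted and under each supplied
#' weighting scheme. Uses the *raw* (un-prepared) baseline values — complete
#' cases per variable, continuous variables uncategorized.
#'
#' @param data,dict Raw cohort data and dictionary (with wave columns).
#' @param wave Wave label defining continuers vs drop-outs.
#' @param weight_sets Named list of `"weight_set"` objects; one weighted
#'   column per entry (may be empty).
#' @param demographic Variable names to compare; default all
#'   `demographic`-role dictionary entries.
#' @param dropout_weighting `"inverse"` (default; drop-outs weighted by
#'   `(1 - p_bar)/(1 - p_hat)` so both groups target the baseline
#'   distribution) or `"none"` (drop-outs unweighted).
#' @param compare `"dropouts"` (default) compares continuers with drop-outs;
#'   `"baseline"` compares weighted continuers with the full baseline
#'   sample.
#' @param threshold Flagging threshold in percent (default 10).
#' @return Tibble of class `"balance_report"`: one row per variable, one
#'   column per scheme; attributes `summary` (max/mean/flags per scheme),
#'   `wave`, `threshold`.
#' @export
balance_table <- function(data, dict, wave, weight_sets = list(),
                          demographic = NULL,
                          dropout_weighting = c("inverse", "none"),
                          compare = c("dropouts", "baseline"),
                          threshold = 10) {
  dropout_weighting <- match.arg(dropout_weighting)
  compare <- match.arg(compare)
  demographic <- demographic %||% candidate_variables(dict, demographic_only = TRUE)
  unknown <- setdiff(demographic, dict$name)
  if (length(unknown) > 0) {
    abort(paste0("Demographic variable(s) not in the dictionary: ",
                 paste(unknown, collapse = ", ")), class = "aw_schema_error")
  }
  wcol <- wave_column(wave)
  if (!wcol %in% names(data)) {
    abort(paste0("Wave indicator '", wcol, "' not present."),
          class = "aw_schema_error")
  }
  group <- data[[wcol]]
  if (all(group == 1)) {
    abort(paste0("Wave '", wave, "' has no drop-outs; balance is undefined."),
          class = "aw_degenerate_error")
  }
  if (length(weight_sets) > 0 &&
      (is.null(names(weight_sets)) || any(!nzchar(names(weight_sets))))) {
    abort("weight_sets must be a named list.", class = "aw_argument_error")
  }

  one_scheme <- function(w) {
    if (compare == "baseline") {
      # weighted continuers vs the (unweighted) full baseline sample
      x_idx <- c(which(group == 1), seq_along(group))
      g <- c(rep(1L, sum(group == 1)), rep(0L, length(group)))
      wts <- c(if (is.null(w)) rep(1, sum(group == 1)) else w[group == 1],
               rep(1, length(group)))
    } else {
      x_idx <- seq_along(group)
      g <- group
      wts <- if (is.null(w)) rep(1, length(group)) else w
    }
    map_dbl(demographic, function(v) {
      x <- data[[v]][x_idx]
      if (dict_vtype(dict, v) == "continuous") {
        standardized_difference_continuous(x, g, wts)
      } else {
        standardized_difference_categorical(x, g, wts)
      }
    })
  }

  out <- tibble(variable = demographic, unweighted = one_scheme(NULL))
  for (nm in names(weight_sets)) {
    w <- balance_weights(weight_sets[[nm]], data,
                         dropout_weighting = dropout_weighting)
    out[[nm]] <- one_scheme(w)
  }
  schemes <- setdiff(names(out), "variable")
  summary <- tibble(
    scheme = schemes,
    max_abs_d = map_dbl(schemes, function(s) max(out[[s]])),
    mean_abs_d = map_dbl(schemes, function(s) mean(out[[s]])),
    n_flagged = map_dbl(schemes, function(s) sum(out[[s]] >= threshold))
  )
  attr(out, "summary") <- summary
  attr(out, "flags") <- lapply(setNames(schemes, schemes),
                               function(s) out$variable[out[[s]] >= threshold])
  attr(out, "wave") <- wave
  attr(out, "threshold") <- threshold
  class(out) <- c("balance_report", class(out))
  out
}

#' Balance across all follow-up waves
#'
#' Prepares the cohort, re-fits the selected variable set for every wave
#' (see [refit_for_wave()]), computes truncated stabilized weights, and
#' returns the long-format table of absolute standardized differences by
#' variable, wave and scheme.
#'
#' @param data,dict Raw cohort data and dictionary (with wave columns).
#' @param variables Selected variable set (or a `"participation_model"`).
#' @param waves Wave labels; default every wave in the dictionary.
#' @param demographic Demographic panel; default the `demographic`-role
#'   variables.
#' @param low_pct,high_pct Truncation percentiles.
#' @param scheme_name Column name for the weighted scheme (default
#'   `"weighted"`).
#' @param ... Passed to [balance_table()].
#' @return Tibble of class `"multiwave_balance"`: `wave`, `variable`,
#'   `scheme`, `abs_std_diff`; attribute `reports` holds the per-wave
#'   `"balance_report"` objects and `models` the per-wave re-fits.
#' @export
multiwave_balance <- function(data, dict, variables, waves = NULL,
                              demographic = NULL, low_pct = 0.5,
                              high_pct = 99.5, scheme_name = "weighted", ...) {
  if (inherits(variables, "participation_model")) variables <- variables$variables
  waves <- waves %||% wave_labels(dict)
  prep <- prepare_cohort(data, dict)
  reports <- list()
  models <- list()
  for (w in waves) {
    rf <- refit_for_wave(variables, prep$data, prep$dict, w,
                         low_pct = low_pct, high_pct = high_pct)
    models[[w]] <- rf$model
    ws <- list(rf$weights)
    names(ws) <- scheme_name
    reports[[w]] <- balance_table(data, dict, w, weight_sets = ws,
                                  demographic = demographic, ...)
  }
  long <- bind_rows(lapply(waves, function(w) {
    reports[[w]] |>
      as_tibble() |>
      tidyr::pivot_longer(-"variable", names_to = "scheme",
                          values_to = "abs_std_diff") |>
      mutate(wave = w, .before = 1)
  }))
  attr(long, "reports") <- reports
  attr(long, "models") <- models
  class(long) <- c("multiwave_balance", class(long))
  long
}
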