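#' Discrimination and calibration of participation models
#'
#' Discrimination is summarised by the area under the ROC curve (equivalently
#' the Mann-Whitney probability that a randomly chosen continuer scores above
#' a randomly chosen drop-out, ties counting one half), with DeLong
#' variance-based confidence intervals and paired tests. Calibration combines
#' the Hosmer-Lemeshow chi-square over predicted-risk deciles, mean
#' calibration (average predicted risk vs observed continuation rate), and a
#' loess calibration curve against the ideal diagonal.
#'
#' @name model-assessment
NULL

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    abort("labels must be 0/1 with no missing values.", class = "aw_argument_error")
  }
  if (length(unique(labels)) < 2) {
    abort("labels contain a single class; both continuers and drop-outs are required.",
          class = "aw_argument_error")
  }
  labels
}

roc_of <- function(scores, labels) {
  pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
            direction = "<", quiet = TRUE)
}

#' Area under the ROC curve with a DeLong confidence interval
#'
#' @param scores Numeric predicted scores (higher = more likely to continue).
#' @param labels 0/1 participation indicator, same length.
#' @param conf_level Confidence level for the DeLong interval.
#' @return One-row tibble of class `"discrimination_report"`: `auroc`,
#'   `ci_low`, `ci_high` (clipped to `[0, 1]`), `n_cases`, `n_controls`.
#' @export
auroc <- function(scores, labels, conf_level = 0.95) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length.", class = "aw_argument_error")
  }
  r <- roc_of(scores, labels)
  a <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                                                 method = "delong")))
  out <- tibble(auroc = a,
                ci_low = max(0, min(ci[1], a)),
                ci_high = min(1, max(ci[3], a)),
                n_cases = sum(labels == 1L),
                n_controls = sum(labels == 0L))
  class(out) <- c("discrimination_report", class(out))
  out
}

#' DeLong paired test for two correlated AUROCs
#'
#' Both score vectors must be computed on the same participants. The z
#' statistic divides the AUC difference by the DeLong structural-component
#' variance of the difference; when that variance is zero and the AUCs are
#' equal (e.g. comparing a model with itself), `z = 0` and `p = 1`.
#'
#' @param scores_a,scores_b Predicted scores from the two models.
#' @param labels Shared 0/1 participation indicator.
#' @return One-row tibble: `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort("scores_a, scores_b and labels must have the same length.",
          class = "aw_argument_error")
  }
  ra <- roc_of(scores_a, labels)
  rb <- roc_of(scores_b, labels)
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  tt <- suppressWarnings(pROC::roc.test(ra, rb, method = "delong", paired = TRUE))
  z <- as.numeric(tt$statistic)
  p <- as.numeric(tt$p.value)
  if (!is.finite(z)) {
    if (isTRUE(all.equal(auc_a, auc_b))) {
      z <- 0; p <- 1
    } else {
      abort("DeLong variance of the AUC difference is zero but the AUCs differ.",
            class = "aw_numeric_error")
    }
  }
  tibble(auc_a = auc_a, auc_b = auc_b, z = z, p = p)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Observations are binned by deciles (generally `n_bins` quantiles) of
#' predicted risk, ties going to the lower bin; bins emptied by ties, or with
#' expected counts of 0 or n, are merged into their lower neighbour with a
#' warning. The statistic sums `(O - E)^2 / E` over both the event and
#' non-event margins of every bin; degrees of freedom are the number of
#' effective bins minus 2.
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param labels 0/1 participation indicator.
#' @param n_bins Number of risk bins (default 10).
#' @return One-row tibble: `statistic`, `df`, `p`, `n_bins_effective`.
#' @export
hosmer_lemeshow <- function(probs, labels, n_bins = 10) {
  labels <- check_binary_labels(labels)
  if (length(probs) != length(labels)) {
    abort("probs and labels must have the same length.", class = "aw_argument_error")
  }
  if (any(probs <= 0) || any(probs >= 1)) {
    abort("probs must lie strictly inside (0, 1).", class = "aw_argument_error")
  }
  breaks <- quantile(probs, seq(0, 1, length.out = n_bins + 1), type = 7,
                     names = FALSE)
  breaks <- unique(breaks)
  if (length(breaks) - 1 < n_bins) {
    warn("Tied predicted risks emptied some bins; merged.",
         class = "aw_bin_merge_warning")
  }
  # right-closed intervals: a value equal to an interior break joins the
  # lower bin
  bin <- cut(probs, breaks = breaks, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  grp <- tibble(bin = bin, p = probs, y = labels) |>
    group_by(.data$bin) |>
    summarise(n = n(), O = sum(.data$y), E = sum(.data$p), .groups = "drop") |>
    arrange(.data$bin)
  # merge degenerate bins (all-event or all-non-event in expectation)
  i <- 1L
  while (i <= nrow(grp)) {
    if (nrow(grp) > 1 && (grp$E[i] < 1e-12 || grp$n[i] - grp$E[i] < 1e-12)) {
      j <- if (i == 1L) 2L else i - 1L
      grp$n[j] <- grp$n[j] + grp$n[i]
      grp$O[j] <- grp$O[j] + grp$O[i]
      grp$E[j] <- grp$E[j] + grp$E[i]
      grp <- grp[-i, ]
      warn("Merged a risk bin with degenerate expected count.",
           class = "aw_bin_merge_warning")
    } else {
      i <- i + 1L
    }
  }
  stat <- sum((grp$O - grp$E)^2 / grp$E +
                ((grp$n - grp$O) - (grp$n - grp$E))^2 / (grp$n - grp$E))
  df <- nrow(grp) - 2L
  p <- if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  tibble(statistic = stat, df = as.integer(df), p = p,
         n_bins_effective = nrow(grp))
}

#' Mean calibration
#'
#' Compares the average predicted risk with the observed event rate. For a
#' maximum-likelihood logistic fit with an intercept, evaluated on its own
#' training data, the two are equal by the score equations.
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 participation indicator.
#' @return One-row tibble: `mean_predicted`, `observed_rate`.
#' @export
mean_calibration <- function(probs, labels) {
  labels <- check_binary_labels(labels)
  if (length(probs) != length(labels)) {
    abort("probs and labels must have the same length.", class = "aw_argument_error")
  }
  tibble(mean_predicted = mean(probs), observed_rate = mean(labels))
}

#' Loess calibration curve
#'
#' Locally weighted regression of the observed outcome on predicted risk,
#' evaluated on an even grid over the observed risk range; the ideal
#' diagonal (intercept 0, slope 1) is returned alongside for plotting.
#'
#' @param probs Predicted probabilities (at least 50 observations).
#' @param labels 0/1 participation indicator.
#' @param span Loess smoother span (default 0.75; affects plots only).
#' @param n_grid Number of grid points.
#' @return Tibble of class `"calibration_curve"`: `predicted`, `observed`
#'   (smoothed), `ideal`.
#' @export
calibration_curve <- function(probs, labels, span = 0.75, n_grid = 100) {
  labels <- check_binary_labels(labels)
  if (length(probs) < 50) {
    abort("calibration_curve needs at least 50 observations.",
          class = "aw_argument_error")
  }
  if (diff(range(probs)) < 1e-12) {
    warn("Predicted risks are constant; returning a single-point curve.",
         class = "aw_degenerate_warning")
    out <- tibble(predicted = probs[1], observed = mean(labels),
                  ideal = probs[1])
    class(out) <- c("calibration_curve", class(out))
    return(out)
  }
  fit <- loess(labels ~ probs, span = span,
               data = data.frame(probs = probs, labels = labels))
  grid <- seq(min(probs), max(probs), length.out = n_grid)
  sm <- predict(fit, newdata = data.frame(probs = grid))
  out <- tibble(predicted = grid, observed = as.numeric(sm), ideal = grid)
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Assess a fitted participation model
#'
#' Convenience wrapper computing the discrimination report, Hosmer-Lemeshow
#' test, mean calibration and calibration curve of a model's predicted
#' probabilities against a wave's participation indicator.
#'
#' @param model A fitted participation model (see [finalize_model()] /
#'   [apriori_model()]).
#' @param data,dict Prepared cohort data and dictionary.
#' @param wave Wave label; defaults to the model's outcome wave.
#' @param n_bins,span Passed to [hosmer_lemeshow()] and [calibration_curve()].
#' @return A list of class `"model_assessment"`: `discrimination`,
#'   `hosmer_lemeshow`, `mean_calibration`, `curve`, `wave`.
#' @export
assess_model <- function(model, data, dict, wave = NULL, n_bins = 10,
                         span = 0.75) {
  wave <- wave %||% model$wave
  labels <- data[[wave_column(wave)]]
  p_hat <- predict_probabilities(model, data)$p_hat
  structure(list(
    discrimination = auroc(p_hat, labels),
    hosmer_lemeshow = hosmer_lemeshow(p_hat, labels, n_bins = n_bins),
    mean_calibration = mean_calibration(p_hat, labels),
    curve = calibration_curve(p_hat, labels, span = span),
    wave = wave
  ), class = "model_assessment")
}
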