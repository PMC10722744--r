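#' Variable selection for participation models
#'
#' Two arms are supported. The *a priori* arm takes a curated variable list
#' as-is and fits an unpenalized logistic participation model. The *LASSO*
#' arm screens each context theme separately with 10-fold cross-validated
#' L1-penalized logistic regression (predictors dummy-encoded and
#' standardized, penalty minimizing mean CV deviance), ranks variables by
#' their largest absolute standardized level coefficient, grows a theme model
#' forward from the top three by AUROC with a paired DeLong gate, pools the
#' theme winners into one more cross-validated LASSO, and keeps the variables
#' with any non-zero coefficient for the final unpenalized fit.
#'
#' @name variable-selection
NULL

# Dummy-encode variables (reference level = first dictionary level dropped)
# and standardize columns to zero mean / unit variance. Constant columns are
# dropped with a warning. Returns the matrix plus a column -> variable map.
encode_predictors <- function(data, dict, variables, standardize = TRUE) {
  cols <- list()
  map <- list()
  for (v in variables) {
    vt <- dict_vtype(dict, v)
    x <- data[[v]]
    if (is.null(x)) abort(paste0("Variable '", v, "' not present in data."),
                          class = "aw_schema_error")
    if (vt == "continuous") {
      cols[[v]] <- as.numeric(x)
      map[[v]] <- tibble(column = v, variable = v, level = NA_character_)
    } else {
      lv <- dict_levels(dict, v)
      lv <- lv[lv %in% unique(x)]  # keep only realised levels
      if (length(lv) < 2) {
        warn(paste0("Variable '", v, "' is constant after encoding; dropped."),
             class = "aw_constant_predictor_warning")
        next
      }
      for (l in lv[-1]) {
        cn <- paste0(v, "=", l)
        cols[[cn]] <- as.numeric(x == l)
        map[[cn]] <- tibble(column = cn, variable = v, level = l)
      }
    }
  }
  if (length(cols) == 0) {
    return(list(x = matrix(numeric(), nrow = nrow(data), ncol = 0),
                map = tibble(column = character(), variable = character(),
                             level = character())))
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warn(paste0("Constant predictor column(s) dropped: ",
                paste(colnames(x)[!keep], collapse = ", ")),
         class = "aw_constant_predictor_warning")
    x <- x[, keep, drop = FALSE]
  }
  if (standardize && ncol(x) > 0) {
    x <- scale(x)
  }
  list(x = x, map = bind_rows(map[colnames(x)]))
}

# Deterministic outcome-stratified fold assignment.
stratified_folds <- function(y, k_folds, seed) {
  foldid <- integer(length(y))
  with_rng(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  foldid
}

#' Cross-validated LASSO logistic screen
#'
#' Dummy-encodes and standardizes the given variables, then fits an
#' L1-penalized logistic regression for wave participation with `k_folds`
#' cross-validation (folds stratified by outcome, deterministic given
#' `seed`), keeping the penalty that minimizes mean cross-validated binomial
#' deviance.
#'
#' @param data,dict Prepared cohort data and dictionary.
#' @param variables Candidate variable names.
#' @param wave Outcome wave label.
#' @param k_folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `"cv_lasso_fit"`: `coefficients` (tibble `column`,
#'   `variable`, `level`, `coefficient` on the standardized dummy scale at
#'   the selected penalty), `lambda` and `wave`.
#' @export
fit_cv_lasso_logistic <- function(data, dict, variables, wave, k_folds = 10,
                                  seed = 1L) {
  y <- check_binary_labels(data[[wave_column(wave)]])
  enc <- encode_predictors(data, dict, variables)
  if (ncol(enc$x) == 0) {
    abort("No usable predictor columns after encoding.", class = "aw_argument_error")
  }
  if (ncol(enc$x) == 1) {
    # glmnet needs >= 2 columns; a single predictor needs no selection
    b <- coef(glm(y ~ enc$x[, 1], family = binomial()))[2]
    coefs <- enc$map |> mutate(coefficient = unname(b))
    return(structure(list(coefficients = coefs, lambda = NA_real_, wave = wave),
                     class = "cv_lasso_fit"))
  }
  foldid <- stratified_folds(y, k_folds, seed)
  cv <- glmnet::cv.glmnet(enc$x, y, family = "binomial", alpha = 1,
                          foldid = foldid, type.measure = "deviance",
                          standardize = FALSE)
  b <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  coefs <- enc$map |> mutate(coefficient = b)
  structure(list(coefficients = coefs, lambda = cv$lambda.min, wave = wave),
            class = "cv_lasso_fit")
}

#' Rank variables by largest absolute level coefficient
#'
#' Each variable is scored by the maximum absolute (standardized-scale)
#' coefficient over its dummy levels — a categorical variable with one
#' influential level is retained whole. Variables scoring exactly zero are
#' excluded; ties are broken by dictionary order.
#'
#' @param fit A `"cv_lasso_fit"` (or its `coefficients` tibble).
#' @param dict Variable dictionary (tie-break order).
#' @return Tibble `variable`, `score`, ordered by decreasing score.
#' @export
rank_variables_by_coefficient <- function(fit, dict) {
  coefs <- if (inherits(fit, "cv_lasso_fit")) fit$coefficients else fit
  scored <- coefs |>
    group_by(.data$variable) |>
    summarise(score = max(abs(.data$coefficient)), .groups = "drop") |>
    filter(.data$score > 0) |>
    mutate(dict_order = match(.data$variable, dict$name)) |>
    arrange(dplyr::desc(.data$score), .data$dict_order) |>
    select("variable", "score")
  scored
}

# Unpenalized logistic fit on dummy-encoded variables, with a
# ridge-stabilized fallback when the ML fit separates or fails to converge.
fit_logistic_model <- function(data, dict, variables, wave, method = "lasso") {
  y <- check_binary_labels(data[[wave_column(wave)]])
  lvls <- setNames(lapply(variables, function(v) dict_levels(dict, v)), variables)
  if (length(variables) == 0) {
    fit <- glm(y ~ 1, family = binomial())
    return(new_participation_model(variables, lvls, wave, method,
                                   intercept = unname(coef(fit)[1]),
                                   coefficients = tibble(
                                     column = character(), variable = character(),
                                     level = character(), estimate = numeric(),
                                     std_error = numeric()),
                                   ridge = FALSE))
  }
  enc <- encode_predictors(data, dict, variables, standardize = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ enc$x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep || !fit$converged || any(!is.finite(coef(fit))) ||
      any(abs(coef(fit)[-1]) > 15)) {
    inform(paste0("ML logistic fit unstable for wave ", wave,
                  "; using a ridge-stabilized fit."),
           class = "aw_ridge_fallback")
    xr <- enc$x
    if (ncol(xr) == 1) xr <- cbind(xr, `.pad` = 0)  # glmnet needs >= 2 cols
    rf <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = FALSE)
    b <- as.numeric(coef(rf))[seq_len(ncol(enc$x) + 1)]
    est <- b[-1]
    icpt <- b[1]
    se <- rep(NA_real_, length(est))
    ridge <- TRUE
  } else {
    cf <- summary(fit)$coefficients
    icpt <- unname(cf[1, 1])
    est <- unname(cf[-1, 1])
    se <- unname(cf[-1, 2])
    ridge <- FALSE
  }
  coefs <- enc$map |> mutate(estimate = est, std_error = se)
  new_participation_model(variables, lvls, wave, method, intercept = icpt,
                          coefficients = coefs, ridge = ridge)
}

new_participation_model <- function(variables, levels, wave, method,
                                    intercept, coefficients, ridge) {
  structure(list(variables = variables, levels = levels, wave = wave,
                 method = method, intercept = intercept,
                 coefficients = coefficients, ridge = ridge),
            class = "participation_model")
}

#' @export
print.participation_model <- function(x, ...) {
  cat("<participation_model> method:", x$method, " wave:", x$wave, "\n",
      length(x$variables), "variable(s),",
      nrow(x$coefficients), "coefficient(s)",
      if (x$ridge) "(ridge-stabilized)" else "", "\n")
  invisible(x)
}

#' Forward AUROC-gated selection within a theme
#'
#' Starts from the top three ranked variables (all of them when fewer), then
#' adds the next-ranked variable one at a time, comparing the grown model's
#' AUROC to the previous one with the paired DeLong test. The first addition
#' whose two-sided p-value exceeds `alpha` stops the walk and that failing
#' variable is excluded from the winner set.
#'
#' @param data,dict Prepared cohort data and dictionary.
#' @param ranked Ranking from [rank_variables_by_coefficient()] (tibble or
#'   character vector, best first).
#' @param wave Outcome wave label.
#' @param alpha Stopping threshold on the DeLong p-value (default 0.05).
#' @return A list of class `"selection_trace"`: `winners` (character),
#'   `trace` (tibble `step`, `variable`, `auroc`, `p`, `action`), `wave`.
#' @export
forward_auc_selection <- function(data, dict, ranked, wave, alpha = 0.05) {
  if (is.data.frame(ranked)) ranked <- ranked$variable
  if (length(ranked) == 0) {
    abort("ranked variable list is empty.", class = "aw_argument_error")
  }
  labels <- check_binary_labels(data[[wave_column(wave)]])
  n_init <- min(3L, length(ranked))
  current <- ranked[seq_len(n_init)]
  fit <- fit_logistic_model(data, dict, current, wave)
  scores <- predict_probabilities(fit, data)$p_hat
  auc_cur <- auroc(scores, labels)$auroc
  trace <- tibble(step = 0L, variable = paste(current, collapse = "+"),
                  auroc = auc_cur, p = NA_real_, action = "initial")
  step <- 0L
  stopped <- FALSE
  for (v in ranked[-seq_len(n_init)]) {
    step <- step + 1L
    cand_fit <- fit_logistic_model(data, dict, c(current, v), wave)
    cand_scores <- predict_probabilities(cand_fit, data)$p_hat
    test <- delong_paired_test(cand_scores, scores, labels)
    if (test$p > alpha) {
      trace <- bind_rows(trace, tibble(step = step, variable = v,
                                       auroc = test$auc_a, p = test$p,
                                       action = "rejected_stop"))
      stopped <- TRUE
      break
    }
    current <- c(current, v)
    scores <- cand_scores
    trace <- bind_rows(trace, tibble(step = step, variable = v,
                                     auroc = test$auc_a, p = test$p,
                                     action = "added"))
  }
  if (!stopped) {
    trace <- bind_rows(trace, tibble(step = step + 1L, variable = NA_character_,
                                     auroc = NA_real_, p = NA_real_,
                                     action = "exhausted"))
  }
  structure(list(winners = current, trace = trace, wave = wave),
            class = "selection_trace")
}

#' Pool theme winners and finalize the model
#'
#' Re-runs the cross-validated LASSO on the union of all theme winner sets,
#' retains every variable with at least one non-zero level coefficient, and
#' fits the final *unpenalized* logistic participation model on the retained
#' set. If the penalized fit zeroes everything, an intercept-only model is
#' returned with a warning.
#'
#' @param data,dict Prepared cohort data and dictionary.
#' @param winners Character vector: union of per-theme winner sets.
#' @param wave Outcome wave label.
#' @param k_folds,seed Passed to [fit_cv_lasso_logistic()].
#' @return A `"participation_model"` with a `selection` element recording the
#'   retained set and the combined penalized coefficients.
#' @export
combine_and_finalize <- function(data, dict, winners, wave, k_folds = 10,
                                 seed = 1L) {
  if (length(winners) == 0) {
    abort("winner set is empty.", class = "aw_argument_error")
  }
  combined <- fit_cv_lasso_logistic(data, dict, winners, wave,
                                    k_folds = k_folds, seed = seed)
  retained <- combined$coefficients |>
    group_by(.data$variable) |>
    summarise(any_nonzero = any(.data$coefficient != 0), .groups = "drop") |>
    filter(.data$any_nonzero) |>
    pull("variable")
  retained <- intersect(winners, retained)  # stable original order
  if (length(retained) == 0) {
    warn("Combined LASSO zeroed every coefficient; falling back to an intercept-only model.",
         class = "aw_empty_model_warning")
  }
  model <- fit_logistic_model(data, dict, retained, wave, method = "lasso")
  model$selection <- list(retained = retained, combined = combined)
  model
}

#' Theme-wise LASSO variable selection
#'
#' Runs the full data-driven arm for one wave: per-theme cross-validated
#' LASSO screen, coefficient ranking, forward AUROC-gated inclusion, then
#' [combine_and_finalize()] on the pooled winners. Themes whose screen
#' retains nothing contribute no winners.
#'
#' @param data,dict Prepared cohort data and dictionary.
#' @param wave Outcome wave label.
#' @param alpha DeLong stopping threshold (default 0.05).
#' @param k_folds CV folds (default 10).
#' @param seed Integer seed; per-theme fold seeds are derived by fixed
#'   offsets.
#' @return A list of class `"lasso_selection"`: `model` (the final
#'   `"participation_model"`), `winners` (named list per theme), `traces`
#'   (named list of `"selection_trace"`), `screens` (per-theme
#'   `"cv_lasso_fit"`).
#' @export
select_variables_lasso <- function(data, dict, wave, alpha = 0.05,
                                   k_folds = 10, seed = 1L) {
  winners <- list()
  traces <- list()
  screens <- list()
  for (th in AW_THEMES) {
    vars <- dict$name[dict$role %in% c("candidate", "demographic") &
                        !is.na(dict$theme) & dict$theme == th]
    if (length(vars) == 0) next
    screen <- fit_cv_lasso_logistic(data, dict, vars, wave, k_folds = k_folds,
                                    seed = seed + match(th, AW_THEMES))
    screens[[th]] <- screen
    ranked <- rank_variables_by_coefficient(screen, dict)
    if (nrow(ranked) == 0) {
      winners[[th]] <- character()
      next
    }
    sel <- forward_auc_selection(data, dict, ranked, wave, alpha = alpha)
    winners[[th]] <- sel$winners
    traces[[th]] <- sel
  }
  pooled <- unique(unlist(winners, use.names = FALSE))
  model <- combine_and_finalize(data, dict, pooled, wave, k_folds = k_folds,
                                seed = seed + 100L)
  structure(list(model = model, winners = winners, traces = traces,
                 screens = screens, wave = wave),
            class = "lasso_selection")
}

#' Default curated (a priori) variable list
#'
#' Eighteen baseline variables in the synthetic dictionary chosen the way a
#' subject-matter panel would: core sociodemographics, pregnancy and
#' conception history, access to prenatal care, physical health and social
#' support, and substance-use history.
#'
#' @return Character vector of 18 variable names.
#' @export
default_apriori_variables <- function() {
  c("education", "ethnicity", "home_ownership", "income", "maternal_age",
    "marital_status", "household_size", "pre_pregnancy_bmi", "time_in_canada",
    "adverse_pregnancy_history", "parity", "maternal_preterm_birth",
    "conception_aids", "prenatal_care_difficulty", "sf12_physical",
    "social_support", "mental_illness_history", "alcohol_drug_dependence")
}

#' A priori variable selection
#'
#' The curated arm performs no data-driven filtering: the supplied list is
#' validated against the dictionary and returned verbatim.
#'
#' @param dict Variable dictionary.
#' @param curated Character vector of variable names (default the 18-variable
#'   list of [default_apriori_variables()]).
#' @return The validated character vector.
#' @export
apriori_select <- function(dict, curated = default_apriori_variables()) {
  if (length(curated) == 0) {
    abort("The curated list is empty; a participation model needs at least one predictor.",
          class = "aw_argument_error")
  }
  unknown <- setdiff(curated, dict$name)
  if (length(unknown) > 0) {
    abort(paste0("Curated variable(s) not in the dictionary: ",
                 paste(unknown, collapse = ", ")), class = "aw_schema_error")
  }
  curated
}

#' Fit the a priori participation model
#'
#' @param data,dict Prepared cohort data and dictionary.
#' @param wave Outcome wave label.
#' @param curated Curated variable list (see [apriori_select()]).
#' @return A `"participation_model"` (method `"apriori"`).
#' @export
apriori_model <- function(data, dict, wave,
                          curated = default_apriori_variables()) {
  vars <- apriori_select(dict, curated)
  fit_logistic_model(data, dict, vars, wave, method = "apriori")
}

#' Finalize a participation model from an explicit variable set
#'
#' @param data,dict Prepared cohort data and dictionary.
#' @param variables Variables to fit (unpenalized logistic regression).
#' @param wave Outcome wave label.
#' @param method Label recorded on the model.
#' @return A `"participation_model"`.
#' @export
finalize_model <- function(data, dict, variables, wave, method = "custom") {
  fit_logistic_model(data, dict, variables, wave, method = method)
}
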