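test_that("a priori selection returns the curated list verbatim or fails loudly", {
  dict <- simulate_cohort(cohort_config(seed = 1))$dict
  sel <- apriori_select(dict)
  expect_length(sel, 18)
  expect_identical(sel, default_apriori_variables())
  expect_error(apriori_select(dict, c("education", "edukation")), "edukation",
               class = "aw_schema_error")
  expect_error(apriori_select(dict, character()), class = "aw_argument_error")
})

test_that("the CV LASSO screen zeroes pure noise and is fold-deterministic", {
  fx <- make_logit_cohort(500, 20, seed = 4)
  fit <- fit_cv_lasso_logistic(fx$data, fx$dict, sprintf("x%02d", 1:20),
                               "3y", seed = 2)
  expect_lt(max(abs(fit$coefficients$coefficient)), 0.05)
  fit2 <- fit_cv_lasso_logistic(fx$data, fx$dict, sprintf("x%02d", 1:20),
                                "3y", seed = 2)
  expect_identical(fit$lambda, fit2$lambda)
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("a strong predictor gets the largest penalized coefficient in most replicates", {
  hits <- 0
  for (s in 1:5) {
    fx <- make_logit_cohort(2000, 20, betas = c(1.5, rep(0, 19)), seed = s)
    fit <- fit_cv_lasso_logistic(fx$data, fx$dict, sprintf("x%02d", 1:20),
                                 "3y", seed = s)
    top <- fit$coefficients$variable[which.max(abs(fit$coefficients$coefficient))]
    if (top == "x01") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("the outcome must not be constant and constant predictors are dropped", {
  fx <- make_logit_cohort(100, 3, seed = 1)
  fx$data$wave_3y_participation <- 1L
  expect_error(fit_cv_lasso_logistic(fx$data, fx$dict, c("x01", "x02", "x03"),
                                     "3y"), class = "aw_argument_error")
  fx2 <- make_logit_cohort(200, 3, seed = 1)
  fx2$data$x02 <- 0
  expect_warning(
    fit_cv_lasso_logistic(fx2$data, fx2$dict, c("x01", "x02", "x03"), "3y"),
    class = "aw_constant_predictor_warning")
})

test_that("variables are ranked by max |level coefficient| with dictionary tie-break", {
  dict <- tibble::tibble(name = c("id", "b_var", "a_var", "c_var"),
                         theme = c(NA, rep("sociodemographic", 3)),
                         vtype = c("categorical", rep("categorical", 3)),
                         levels = c(NA, "x|y|z", "x|y", "x|y"),
                         role = c("id", rep("candidate", 3)))
  coefs <- tibble::tibble(
    column = c("a_var=y", "b_var=y", "b_var=z", "c_var=y"),
    variable = c("a_var", "b_var", "b_var", "c_var"),
    level = c("y", "y", "z", "y"),
    coefficient = c(0.5, 0.9, 0.1, 0))
  ranked <- rank_variables_by_coefficient(coefs, dict)
  expect_equal(ranked$variable, c("b_var", "a_var"))  # zero scores excluded
  expect_equal(ranked$score, c(0.9, 0.5))
  # tie broken by dictionary order (b_var precedes a_var in the dictionary)
  coefs$coefficient <- c(0.5, 0.5, 0.1, 0)
  expect_equal(rank_variables_by_coefficient(coefs, dict)$variable,
               c("b_var", "a_var"))
})

test_that("forward selection keeps prefixes: a top-3 ranking needs no comparison", {
  fx <- make_logit_cohort(800, 3, betas = c(1, 0.8, 0.6), seed = 6)
  sel <- forward_auc_selection(fx$data, fx$dict, c("x01", "x02", "x03"), "3y")
  expect_identical(sel$winners, c("x01", "x02", "x03"))
  expect_equal(sum(sel$trace$action %in% c("added", "rejected_stop")), 0)
})

test_that("forward selection stops on a noise addition and admits a true signal", {
  stop_hits <- 0
  admit_hits <- 0
  for (s in 1:5) {
    # x01-x03 strong, x04 pure noise
    fx <- make_logit_cohort(3351, 5, betas = c(1, 0.9, 0.8, 0, 0), seed = s)
    sel <- forward_auc_selection(fx$data, fx$dict,
                                 sprintf("x%02d", 1:4), "3y")
    if (identical(sel$winners, c("x01", "x02", "x03"))) stop_hits <- stop_hits + 1
    expect_identical(sel$winners,
                     sprintf("x%02d", seq_along(sel$winners)))  # prefix property

    # now x04 carries true log-odds 1.0
    fx2 <- make_logit_cohort(3351, 5, betas = c(1, 0.9, 0.8, 1, 0),
                             seed = s + 100)
    sel2 <- forward_auc_selection(fx2$data, fx2$dict,
                                  sprintf("x%02d", 1:4), "3y")
    if ("x04" %in% sel2$winners) admit_hits <- admit_hits + 1
  }
  expect_gte(stop_hits, 3)
  expect_gte(admit_hits, 4)
})

test_that("the selection trace records the walk with exactly one terminal action", {
  fx <- make_logit_cohort(1500, 6, betas = c(1, 0.9, 0.8, 0.7, 0, 0), seed = 9)
  sel <- forward_auc_selection(fx$data, fx$dict, sprintf("x%02d", 1:6), "3y")
  tr <- tidy(sel)
  expect_equal(tr$action[1], "initial")
  expect_equal(sum(tr$action %in% c("rejected_stop", "exhausted")), 1)
  aucs <- tr$auroc[tr$action %in% c("initial", "added")]
  expect_true(all(aucs >= 0.45 & aucs <= 1))
})

test_that("combine_and_finalize keeps disjoint strong signals and falls back on pure noise", {
  fx <- make_logit_cohort(2500, 10, betas = c(1.2, rep(0, 8), 1.2), seed = 12)
  model <- combine_and_finalize(fx$data, fx$dict, sprintf("x%02d", 1:10), "3y",
                                seed = 1)
  expect_true(all(c("x01", "x10") %in% model$selection$retained))
  expect_s3_class(model, "participation_model")
  expect_true(all(is.finite(model$coefficients$estimate)))

  fx0 <- make_logit_cohort(300, 8, seed = 13)
  expect_warning(
    m0 <- combine_and_finalize(fx0$data, fx0$dict, sprintf("x%02d", 1:8),
                               "3y", seed = 1),
    class = "aw_empty_model_warning")
  expect_length(m0$variables, 0)
  p <- predict_probabilities(m0, fx0$data)
  expect_equal(length(unique(p$p_hat)), 1)
})

test_that("the theme-wise LASSO arm finds the planted dropout predictors end-to-end", {
  sim <- simulate_cohort(cohort_config(seed = 6))
  prep <- prepare_cohort(sim$data, sim$dict)
  sel <- select_variables_lasso(prep$data, prep$dict, "3y", seed = 6)
  expect_true(all(names(default_dropout_effects()) %in% sel$model$variables))
  # winner sets are prefixes of each theme ranking
  for (th in names(sel$traces)) {
    ranked <- rank_variables_by_coefficient(sel$screens[[th]], prep$dict)
    k <- length(sel$traces[[th]]$winners)
    expect_identical(sel$traces[[th]]$winners, ranked$variable[seq_len(k)])
  }
  expect_equal(sel$model$method, "lasso")
  expect_gt(length(sel$model$variables), 4)
  expect_lt(length(sel$model$variables), 50)
})
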