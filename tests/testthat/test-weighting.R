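test_that("predicted probabilities match the closed-form logistic by hand", {
  set.seed(2)
  n <- 400
  data <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:n),
    x01 = rnorm(n),
    grp = sample(c("a", "b"), n, TRUE),
    wave_3y_participation = rbinom(n, 1, 0.6))
  dict <- tibble::tibble(
    name = c("participant_id", "x01", "grp", "wave_3y_participation"),
    theme = c(NA, "sociodemographic", "sociodemographic", NA),
    vtype = c("categorical", "continuous", "categorical", "categorical"),
    levels = c(NA, NA, "a|b", NA),
    role = c("id", "candidate", "candidate", "wave"))
  m <- finalize_model(data, dict, c("x01", "grp"), "3y")
  p <- predict_probabilities(m, data)
  cf <- tidy(m)
  by_hand <- plogis(cf$estimate[cf$term == "(Intercept)"] +
                      cf$estimate[cf$term == "x01"] * data$x01 +
                      cf$estimate[cf$term == "grp=b"] * (data$grp == "b"))
  expect_equal(p$p_hat, by_hand, tolerance = 1e-12)
  # matches glm's own fitted values
  gg <- glm(wave_3y_participation ~ x01 + (grp == "b"), family = binomial(),
            data = data)
  expect_equal(p$p_hat, unname(fitted(gg)), tolerance = 1e-8)

  # link monotonicity: raising a positive-coefficient predictor raises p_hat
  b1 <- cf$estimate[cf$term == "x01"]
  d2 <- data
  d2$x01 <- d2$x01 + sign(b1)
  expect_true(all(predict_probabilities(m, d2)$p_hat >= p$p_hat))

  # an intercept-only model on a balanced outcome predicts ~0.5 for everyone
  d3 <- data
  d3$wave_3y_participation <- rep(c(0L, 1L), n / 2)
  m0 <- finalize_model(d3, dict, character(), "3y")
  expect_equal(unique(predict_probabilities(m0, d3)$p_hat), 0.5,
               tolerance = 1e-9)
})

test_that("unseen categorical levels at prediction time map to the reference level", {
  data <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:200),
    grp = rep(c("a", "b"), 100),
    wave_3y_participation = rep(c(0L, 1L, 1L, 0L), 50))
  dict <- tibble::tibble(
    name = c("participant_id", "grp", "wave_3y_participation"),
    theme = c(NA, "sociodemographic", NA),
    vtype = c("categorical", "categorical", "categorical"),
    levels = c(NA, "a|b|c", NA),
    role = c("id", "candidate", "wave"))
  m <- finalize_model(data, dict, "grp", "3y")
  newdata <- data
  newdata$grp[1] <- "c"
  expect_warning(p <- predict_probabilities(m, newdata),
                 class = "aw_unseen_level_warning")
  ref <- predict_probabilities(m, data)$p_hat[data$grp == "a"][1]
  expect_equal(p$p_hat[1], ref)
})

test_that("stabilized weights are exactly 1 when p_hat equals the marginal rate", {
  part <- rep(c(1L, 0L), c(6, 4))
  ws <- stabilized_weights(rep(0.6, 10), part)
  expect_equal(ws$sw, rep(1, 10))
  expect_equal(attr(ws, "p_bar"), 0.6)
})

test_that("the saturated two-stratum worked example gives the known weights", {
  # stratum A: n=4, 2 respond (p_hat 0.5); stratum B: n=4, 4 respond (p_hat 1)
  p_hat <- c(rep(0.5, 4), rep(1, 4))
  part <- c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L)
  ws <- stabilized_weights(p_hat, part)
  resp <- ws$sw[ws$participation == 1]
  expect_equal(sort(resp), sort(c(1.5, 1.5, 0.75, 0.75, 0.75, 0.75)))
  expect_equal(mean(resp), 1, tolerance = 1e-12)
  expect_error(stabilized_weights(c(0, 0.5), c(1L, 0L)),
               class = "aw_numeric_error")
  expect_error(stabilized_weights(c(1.2, 0.5), c(1L, 0L)),
               class = "aw_numeric_error")
})

test_that("stabilized weights average ~1 over responders under an ML fit at n = 3,351", {
  sim <- simulate_cohort(cohort_config(seed = 19))
  prep <- prepare_cohort(sim$data, sim$dict)
  m <- apriori_model(prep$data, prep$dict, "3y")
  ws <- compute_weights(m, prep$data)
  resp <- ws[ws$participation == 1, ]
  expect_lt(abs(mean(resp$sw) - 1), 0.02)
  # stabilization shrinks variance relative to raw 1/p_hat weights
  expect_lt(var(resp$sw), var(1 / resp$p_hat))
})

test_that("truncation clamps exactly the weights outside the percentile bounds", {
  ws0 <- stabilized_weights(rep(0.6, 50), rep(c(1L, 0L), c(30, 20)))
  t0 <- truncate_weights(ws0)
  expect_equal(t0$sw_trunc, t0$sw)
  expect_equal(sum(t0$altered), 0L)

  set.seed(44)
  p_hat <- runif(1000, 0.05, 0.95)
  part <- rbinom(1000, 1, p_hat)
  ws <- stabilized_weights(p_hat, part)
  tr <- truncate_weights(ws, 0.5, 99.5)
  # sort-and-count oracle for the altered set
  bounds <- quantile(ws$sw, c(0.005, 0.995), type = 7, names = FALSE)
  expect_equal(sum(tr$altered), sum(ws$sw < bounds[1] | ws$sw > bounds[2]))
  expect_true(all(tr$sw_trunc >= bounds[1] - 1e-12 &
                    tr$sw_trunc <= bounds[2] + 1e-12))
  expect_identical(which(tr$altered), which(tr$sw != tr$sw_trunc))
  expect_lte(max(tr$sw_trunc), max(tr$sw))
  # re-truncation at the same percentiles is idempotent: exactly so under
  # the inverse-CDF quantile convention, to interpolation error under the
  # default
  ws2 <- stabilized_weights(tr$p_hat, tr$participation)
  ws2$sw <- tr$sw_trunc
  tr2 <- truncate_weights(ws2, 0.5, 99.5)
  expect_equal(tr2$sw_trunc, tr$sw_trunc, tolerance = 1e-3)
  tr1a <- truncate_weights(ws, 0.5, 99.5, qtype = 1)
  ws3 <- stabilized_weights(tr1a$p_hat, tr1a$participation)
  ws3$sw <- tr1a$sw_trunc
  tr1b <- truncate_weights(ws3, 0.5, 99.5, qtype = 1)
  expect_identical(tr1b$sw_trunc, tr1a$sw_trunc)
  expect_error(truncate_weights(ws, 99, 1), class = "aw_argument_error")
})

test_that("truncating a heavy upper tail pulls the responder mean toward 1", {
  p_hat <- c(rep(0.7, 996), rep(0.02, 4))
  part <- c(rep(1L, 700), rep(0L, 296), 1L, 1L, 0L, 0L)
  ws <- stabilized_weights(p_hat, part)
  tr <- truncate_weights(ws, 0.5, 99.5)
  resp_before <- ws$sw[ws$participation == 1]
  resp_after <- tr$sw_trunc[tr$participation == 1]
  expect_gt(mean(resp_before), 1.05)
  expect_lt(abs(mean(resp_after) - 1), abs(mean(resp_before) - 1))
  expect_lt(max(resp_after), max(resp_before))
})

test_that("one-sided truncation is available by setting low_pct = 0", {
  set.seed(45)
  ws <- stabilized_weights(runif(500, 0.05, 0.9), rbinom(500, 1, 0.6))
  tr <- truncate_weights(ws, low_pct = 0, high_pct = 99.5)
  expect_equal(min(tr$sw_trunc), min(ws$sw))
  expect_lt(max(tr$sw_trunc), max(ws$sw))
})

test_that("re-fitting for the same wave is idempotent and waves stay stable", {
  sim <- simulate_cohort(cohort_config(seed = 25))
  prep <- prepare_cohort(sim$data, sim$dict)
  vars <- c("education", "home_ownership", "maternal_age", "smoking_history",
            "anxiety_symptoms")
  m3 <- finalize_model(prep$data, prep$dict, vars, "3y")
  rf <- refit_for_wave(m3, prep$data, prep$dict, "3y")
  expect_equal(rf$model$coefficients$estimate, m3$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(rf$model$intercept, m3$intercept, tolerance = 1e-10)

  # the dropout mechanism is shared across waves, so discrimination is stable
  a3 <- assess_model(m3, prep$data, prep$dict, wave = "3y")
  rf5 <- refit_for_wave(m3, prep$data, prep$dict, "5y")
  a5 <- assess_model(rf5$model, prep$data, prep$dict, wave = "5y")
  expect_lt(abs(a3$discrimination$auroc - a5$discrimination$auroc), 0.05)
})

test_that("re-fitted coefficients track a changed dropout mechanism", {
  cfg <- small_config(n = 12000, seed = 33, wave_targets = c("3y" = 0.6))
  base <- generate_baseline(cfg)
  eff_a <- list(education = list(levels = c(less_hs = -0.8, hs = -0.3,
                                            college = 0.1, university = 0.6),
                                 missing = 0))
  eff_b <- list(smoking_history = list(levels = c(never = 0.6, former = 0,
                                                  current = -0.8),
                                       missing = 0))
  simA <- simulate_participation(base$data, base$dict, eff_a,
                                 c("3y" = 0.6), seed = 1)
  simB <- simulate_participation(base$data, base$dict, eff_b,
                                 c("3y" = 0.6), seed = 2)
  prepA <- prepare_cohort(simA$data, simA$dict)
  prepB <- prepare_cohort(simB$data, simB$dict)
  vars <- c("education", "smoking_history")
  mA <- finalize_model(prepA$data, prepA$dict, vars, "3y")
  mB <- finalize_model(prepB$data, prepB$dict, vars, "3y")
  spread <- function(m, v) {
    est <- m$coefficients$estimate[m$coefficients$variable == v &
                                     m$coefficients$level != "missing"]
    diff(range(c(0, est)))
  }
  expect_gt(spread(mA, "education"), spread(mB, "education") + 0.3)
  expect_gt(spread(mB, "smoking_history"), spread(mA, "smoking_history") + 0.3)
})
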