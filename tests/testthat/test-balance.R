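test_that("standardized differences match closed forms", {
  # identical distributions
  x <- rep(c(1, 2, 3), 20)
  g <- rep(c(1, 0), 30)
  expect_equal(standardized_difference_continuous(x, g), 0)
  # means 1 vs 0, both SDs exactly 1 -> 100%
  s <- 1 / sqrt(2)
  x2 <- c(1 - s, 1 + s, -s, s)
  g2 <- c(1, 1, 0, 0)
  expect_equal(standardized_difference_continuous(x2, g2), 100,
               tolerance = 1e-12)
  # binary prevalences 50% vs 30% -> |0.2| / sqrt(0.23) = 41.7%
  x3 <- c(rep(c("yes", "no"), c(50, 50)), rep(c("yes", "no"), c(30, 70)))
  g3 <- rep(c(1, 0), c(100, 100))
  expect_equal(standardized_difference_categorical(x3, g3),
               100 * 0.2 / sqrt(0.23), tolerance = 1e-12)
})

test_that("standardized differences agree with an independent direct-formula oracle", {
  set.seed(71)
  for (i in 1:10) {
    n <- 300
    g <- rbinom(n, 1, 0.55)
    x <- rnorm(n) + 0.3 * g
    x[sample(n, 12)] <- NA
    w <- runif(n, 0.3, 3)
    expect_equal(standardized_difference_continuous(x, g),
                 oracle_sd_cont(x, g), tolerance = 1e-12)
    expect_equal(standardized_difference_continuous(x, g, w),
                 oracle_sd_cont(x, g, w), tolerance = 1e-12)
    xc <- sample(c("a", "b", "c"), n, TRUE, prob = c(0.5, 0.3, 0.2))
    expect_equal(standardized_difference_categorical(xc, g),
                 oracle_sd_cat(xc, g), tolerance = 1e-12)
    expect_equal(standardized_difference_categorical(xc, g, w),
                 oracle_sd_cat(xc, g, w), tolerance = 1e-12)
    # |d| is invariant under swapping the group labels
    expect_equal(standardized_difference_continuous(x, 1 - g),
                 standardized_difference_continuous(x, g), tolerance = 1e-12)
  }
})

test_that("a multi-level variable scores the max over its level dichotomies", {
  set.seed(72)
  x <- sample(c("a", "b", "c"), 400, TRUE, prob = c(0.45, 0.35, 0.2))
  g <- rbinom(400, 1, 0.5)
  per_level <- vapply(c("a", "b", "c"), function(l) {
    standardized_difference_categorical(ifelse(x == l, "hit", "rest"), g)
  }, 0)
  expect_equal(standardized_difference_categorical(x, g), max(per_level),
               tolerance = 1e-12)
})

test_that("degenerate variables: equal constant means give 0, unequal error", {
  g <- rep(c(1, 0), 10)
  expect_equal(standardized_difference_continuous(rep(2, 20), g), 0)
  x <- rep(c(5, 7), each = 10)  # constant within group, different across
  expect_error(standardized_difference_continuous(x, c(rep(1, 10), rep(0, 10))),
               class = "aw_numeric_error")
})

test_that("a saturated participation model balances its covariate exactly", {
  # one discrete covariate, weights from the saturated (one-factor) model
  set.seed(73)
  n <- 900
  data <- tibble::tibble(
    participant_id = sprintf("P%04d", 1:n),
    grp = sample(c("a", "b", "c"), n, TRUE, prob = c(0.5, 0.3, 0.2)))
  p_true <- c(a = 0.75, b = 0.55, c = 0.35)[data$grp]
  data$wave_3y_participation <- rbinom(n, 1, p_true)
  dict <- tibble::tibble(
    name = c("participant_id", "grp", "wave_3y_participation"),
    theme = c(NA, "sociodemographic", NA),
    vtype = c("categorical", "categorical", "categorical"),
    levels = c(NA, "a|b|c", NA),
    role = c("id", "demographic", "wave"))
  m <- finalize_model(data, dict, "grp", "3y")
  ws <- compute_weights(m, data, low_pct = 0, high_pct = 100)
  bt <- balance_table(data, dict, "3y", weight_sets = list(saturated = ws))
  expect_gt(bt$unweighted, 10)
  expect_equal(bt$saturated, 0, tolerance = 1e-8)
  # the same exactness holds against the baseline total
  bt2 <- balance_table(data, dict, "3y", weight_sets = list(saturated = ws),
                       compare = "baseline")
  expect_equal(bt2$saturated, 0, tolerance = 1e-8)
})

test_that("balance_table flags, summarises, and validates its inputs", {
  sim <- simulate_cohort(cohort_config(seed = 3))
  bt <- balance_table(sim$data, sim$dict, "3y")
  expect_equal(nrow(bt), 15)
  expect_equal(sort(bt$variable),
               sort(candidate_variables(sim$dict, demographic_only = TRUE)))
  s <- attr(bt, "summary")
  expect_equal(s$max_abs_d, max(bt$unweighted))
  expect_equal(s$n_flagged, sum(bt$unweighted >= 10))
  expect_setequal(attr(bt, "flags")$unweighted,
                  bt$variable[bt$unweighted >= 10])
  expect_error(balance_table(sim$data, sim$dict, "3y",
                             demographic = "not_a_var"),
               class = "aw_schema_error")
  nodrop <- sim$data
  nodrop$wave_3y_participation <- 1L
  expect_error(balance_table(nodrop, sim$dict, "3y"),
               class = "aw_degenerate_error")
  expect_s3_class(autoplot(bt), "ggplot")
})

test_that("weights from a correctly specified model restore balance in most replicates", {
  wins <- 0
  for (s in 1:3) {
    sim <- simulate_cohort(small_config(n = 2500, seed = s))
    prep <- prepare_cohort(sim$data, sim$dict)
    m <- finalize_model(prep$data, prep$dict, names(default_dropout_effects()),
                        "3y")
    ws <- compute_weights(m, prep$data)
    bt <- balance_table(sim$data, sim$dict, "3y",
                        weight_sets = list(weighted = ws))
    if (max(bt$weighted) < max(bt$unweighted)) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("multiwave balance reduces to balance_table on a single wave", {
  sim <- simulate_cohort(small_config(n = 1500, seed = 14))
  vars <- names(default_dropout_effects())
  mw <- multiwave_balance(sim$data, sim$dict, vars, waves = "3y")
  expect_setequal(unique(mw$wave), "3y")
  rep1 <- attr(mw, "reports")[["3y"]]
  prep <- prepare_cohort(sim$data, sim$dict)
  rf <- refit_for_wave(vars, prep$data, prep$dict, "3y")
  bt <- balance_table(sim$data, sim$dict, "3y",
                      weight_sets = list(weighted = rf$weights))
  expect_equal(as.data.frame(rep1), as.data.frame(bt), tolerance = 1e-12)
  g <- glance(mw)
  expect_setequal(g$scheme, c("unweighted", "weighted"))
  expect_s3_class(autoplot(mw), "ggplot")
})
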