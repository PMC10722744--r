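#' Synthetic multi-wave pregnancy cohort
#'
#' The study data this pipeline was designed around (a pregnancy cohort of
#' 3,351 participants, 127 baseline variables across seven context themes,
#' four follow-up waves with covariate-driven attrition) are not publicly
#' available, so the package ships a generator that emulates their statistical
#' structure: mixed categorical/continuous baseline variables with
#' within-theme correlation induced by a shared latent factor, item
#' missingness, and monotone wave participation driven by a sparse logistic
#' dropout model on baseline values. The true dropout model is returned
#' verbatim so parameter-recovery tests have an oracle.
#'
#' @name synthetic-cohort
NULL

# Run code with a private, restorable RNG state.
with_rng <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

default_theme_allocation <- function() {
  c(sociodemographic = 30L,
    pregnancy_history = 18L,
    conception_history = 15L,
    prenatal_care = 15L,
    lifestyle_health_care = 17L,
    mental_health_social_support = 17L,
    smoking_drug_alcohol = 15L)
}

# Named variables with recognisable analogues; fillers complete each theme.
named_variable_plan <- function() {
  v <- function(name, theme, vtype, levels = NULL, probs = NULL,
                mean = 0, sd = 1, role = "candidate") {
    tibble(name = name, theme = theme, vtype = vtype,
           levels = list(levels), probs = list(probs),
           mean = mean, sd = sd, role = role)
  }
  bind_rows(
    v("education", "sociodemographic", "categorical",
      c("less_hs", "hs", "college", "university"),
      c(0.08, 0.22, 0.35, 0.35), role = "demographic"),
    v("income", "sociodemographic", "categorical",
      c("lt_60k", "ge_60k"), c(0.30, 0.70), role = "demographic"),
    v("home_ownership", "sociodemographic", "categorical",
      c("rent", "own"), c(0.35, 0.65), role = "demographic"),
    v("maternal_age", "sociodemographic", "continuous",
      mean = 31, sd = 4.5, role = "demographic"),
    v("paternal_age", "sociodemographic", "continuous",
      mean = 33, sd = 5.5, role = "demographic"),
    v("ethnicity", "sociodemographic", "categorical",
      c("white", "asian", "other"), c(0.70, 0.18, 0.12), role = "demographic"),
    v("marital_status", "sociodemographic", "categorical",
      c("married_cohabiting", "single", "other"), c(0.88, 0.08, 0.04),
      role = "demographic"),
    v("household_size", "sociodemographic", "continuous",
      mean = 3, sd = 1.1, role = "demographic"),
    v("new_canadian", "sociodemographic", "categorical",
      c("no", "yes"), c(0.82, 0.18), role = "demographic"),
    v("food_insecurity", "sociodemographic", "categorical",
      c("no", "yes"), c(0.92, 0.08), role = "demographic"),
    v("pre_pregnancy_bmi", "sociodemographic", "continuous",
      mean = 24.5, sd = 4.8, role = "demographic"),
    v("time_in_canada", "sociodemographic", "categorical",
      c("born_in_canada", "gt_5y", "le_5y"), c(0.78, 0.13, 0.09)),
    v("adverse_pregnancy_history", "pregnancy_history", "categorical",
      c("no", "yes"), c(0.68, 0.32)),
    v("parity", "pregnancy_history", "categorical",
      c("nulliparous", "primiparous", "multiparous"), c(0.55, 0.32, 0.13),
      role = "demographic"),
    v("previous_pregnancies", "pregnancy_history", "categorical",
      c("0", "1", "2plus"), c(0.45, 0.30, 0.25)),
    v("maternal_preterm_birth", "pregnancy_history", "categorical",
      c("no", "yes"), c(0.90, 0.10)),
    v("conception_aids", "conception_history", "categorical",
      c("no", "yes"), c(0.88, 0.12)),
    v("artificial_insemination", "conception_history", "categorical",
      c("no", "yes"), c(0.96, 0.04)),
    v("fertility_aids_count", "conception_history", "categorical",
      c("0", "1", "2plus"), c(0.88, 0.08, 0.04)),
    v("trying_to_conceive", "conception_history", "categorical",
      c("no", "yes"), c(0.30, 0.70)),
    v("conception_advice", "conception_history", "categorical",
      c("no", "yes"), c(0.72, 0.28)),
    v("prenatal_care_difficulty", "prenatal_care", "categorical",
      c("no", "yes"), c(0.91, 0.09)),
    v("prenatal_visits", "prenatal_care", "continuous", mean = 10, sd = 3),
    v("first_prenatal_visit_ga", "prenatal_care", "continuous",
      mean = 9.5, sd = 3.2),
    v("dentist_past_year", "prenatal_care", "categorical",
      c("no", "yes"), c(0.35, 0.65)),
    v("fruit_veg_consumption", "lifestyle_health_care", "categorical",
      c("low", "medium", "high"), c(0.25, 0.45, 0.30)),
    v("provider_visit_after_pregnancy", "lifestyle_health_care", "categorical",
      c("no", "yes"), c(0.12, 0.88)),
    v("sf12_physical", "mental_health_social_support", "continuous",
      mean = 48, sd = 9),
    v("sf12_mental", "mental_health_social_support", "continuous",
      mean = 50, sd = 9.5),
    v("social_support", "mental_health_social_support", "continuous",
      mean = 76, sd = 10),
    v("partner_support", "mental_health_social_support", "categorical",
      c("yes", "no"), c(0.93, 0.07)),
    v("mental_illness_history", "mental_health_social_support", "categorical",
      c("no", "yes"), c(0.70, 0.30)),
    v("anxiety_symptoms", "mental_health_social_support", "categorical",
      c("no", "yes"), c(0.75, 0.25), role = "demographic"),
    v("depression_symptoms", "mental_health_social_support", "categorical",
      c("no", "yes"), c(0.84, 0.16), role = "demographic"),
    v("perceived_stress", "mental_health_social_support", "continuous",
      mean = 15, sd = 6),
    v("smoking_history", "smoking_drug_alcohol", "categorical",
      c("never", "former", "current"), c(0.55, 0.25, 0.20),
      role = "demographic"),
    v("cigarettes_per_day", "smoking_drug_alcohol", "continuous",
      mean = 1.2, sd = 3),
    v("alcohol_drinks_per_day", "smoking_drug_alcohol", "continuous",
      mean = 0.6, sd = 1.1),
    v("drug_use_days_per_week", "smoking_drug_alcohol", "continuous",
      mean = 0.3, sd = 1),
    v("alcohol_drug_dependence", "smoking_drug_alcohol", "categorical",
      c("no", "yes"), c(0.93, 0.07))
  )
}

# Complete the per-theme variable plan up to the requested allocation with
# generic filler variables (cycling 2/3/4-level categoricals and continuous).
build_variable_plan <- function(theme_allocation) {
  named <- named_variable_plan()
  plans <- list()
  for (th in names(theme_allocation)) {
    k <- theme_allocation[[th]]
    base <- named[named$theme == th, ]
    base <- base[seq_len(min(nrow(base), k)), ]
    n_fill <- k - nrow(base)
    if (n_fill > 0) {
      fill <- purrr::map(seq_len(n_fill), function(i) {
        kind <- (i - 1L) %% 4L
        name <- paste0(th, "_q", sprintf("%02d", i))
        if (kind == 0L) {
          tibble(name = name, theme = th, vtype = "continuous",
                 levels = list(NULL), probs = list(NULL),
                 mean = 0, sd = 1, role = "candidate")
        } else {
          nl <- kind + 1L
          tibble(name = name, theme = th, vtype = "categorical",
                 levels = list(paste0("L", seq_len(nl))),
                 probs = list(rep(1 / nl, nl)),
                 mean = 0, sd = 1, role = "candidate")
        }
      })
      base <- bind_rows(base, bind_rows(fill))
    }
    plans[[th]] <- base
  }
  bind_rows(plans)
}

#' Default true dropout model
#'
#' The sparse logistic model that drives attrition in the default synthetic
#' scenario. Five baseline variables carry signal (education, home ownership,
#' maternal age, smoking history, anxiety symptoms — analogues of the factors
#' the attrition literature repeatedly implicates), with effect magnitudes set
#' so that the unweighted maximum absolute standardized difference between
#' continuers and drop-outs lands in the 25–30% band at n = 3,351. Missing
#' baseline cells contribute a dedicated missing-indicator effect.
#'
#' @return Named list of per-variable effects. Categorical entries carry a
#'   named `levels` vector of per-level log-odds contributions; continuous
#'   entries a `beta` per standard deviation of the observed values; both an
#'   effect for `missing` cells.
#' @export
default_dropout_effects <- function() {
  list(
    education = list(levels = c(less_hs = -0.36, hs = -0.16, college = 0.03,
                                university = 0.22), missing = -0.2),
    home_ownership = list(levels = c(rent = -0.21, own = 0.16), missing = -0.2),
    maternal_age = list(steps = c(-0.34, -0.11, 0.01, 0.16, 0.34),
                        missing = -0.2),
    smoking_history = list(levels = c(never = 0.23, former = 0, current = -0.50),
                           missing = -0.2),
    anxiety_symptoms = list(levels = c(no = 0.15, yes = -0.43), missing = -0.2)
  )
}

#' Generator configuration
#'
#' Defaults reproduce the scale of the motivating cohort: 3,351 participants,
#' 127 baseline variables over seven themes, per-variable item missingness
#' between 0 and 4.4%, four follow-up waves (3y/5y/8y/covid) with marginal
#' continuation targets 0.594/0.55/0.50/0.45 and monotone attrition.
#'
#' @param n_participants Number of participants.
#' @param theme_allocation Named integer vector: variables per theme (names
#'   must be the seven theme labels; see [aw_themes()]).
#' @param missing_rate_range Length-2 vector; per-variable item-missingness
#'   probabilities are drawn uniformly from this range.
#' @param wave_targets Named numeric vector of marginal continuation
#'   proportions per wave (all in (0, 1), names become wave labels).
#' @param dropout_effects True dropout model; see [default_dropout_effects()].
#'   Use an empty list for completely-at-random attrition.
#' @param within_theme_correlation Pairwise latent correlation shared by
#'   variables in a theme.
#' @param monotone If `TRUE` (default) a participant lost at one wave stays
#'   lost at all later waves.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A validated config list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 3351L,
                          theme_allocation = default_theme_allocation(),
                          missing_rate_range = c(0, 0.044),
                          wave_targets = c("3y" = 0.594, "5y" = 0.55,
                                           "8y" = 0.50, "covid" = 0.45),
                          dropout_effects = default_dropout_effects(),
                          within_theme_correlation = 0.25,
                          monotone = TRUE,
                          seed = 1L) {
  if (n_participants < 2) abort("n_participants must be at least 2.",
                                class = "aw_config_error")
  if (!setequal(names(theme_allocation), AW_THEMES)) {
    abort("theme_allocation must be named by the seven context themes.",
          class = "aw_config_error")
  }
  if (any(theme_allocation < 0)) {
    abort("theme_allocation counts must be non-negative.", class = "aw_config_error")
  }
  if (length(missing_rate_range) != 2 || any(missing_rate_range < 0) ||
      any(missing_rate_range >= 1) || missing_rate_range[1] > missing_rate_range[2]) {
    abort("missing_rate_range must be an increasing pair in [0, 1).",
          class = "aw_config_error")
  }
  if (is.null(names(wave_targets)) || any(!nzchar(names(wave_targets)))) {
    abort("wave_targets must be named by wave labels.", class = "aw_config_error")
  }
  if (any(wave_targets <= 0) || any(wave_targets >= 1)) {
    abort("wave_targets must lie strictly inside (0, 1).", class = "aw_config_error")
  }
  if (within_theme_correlation < 0 || within_theme_correlation >= 1) {
    abort("within_theme_correlation must be in [0, 1).", class = "aw_config_error")
  }
  plan <- build_variable_plan(theme_allocation[AW_THEMES])
  unknown <- setdiff(names(dropout_effects), plan$name)
  if (length(unknown) > 0) {
    abort(paste0("dropout_effects reference undeclared variable(s): ",
                 paste(unknown, collapse = ", ")), class = "aw_config_error")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    theme_allocation = theme_allocation[AW_THEMES],
    n_variables = sum(theme_allocation),
    missing_rate_range = missing_rate_range,
    wave_targets = wave_targets,
    dropout_effects = dropout_effects,
    within_theme_correlation = within_theme_correlation,
    monotone = monotone,
    seed = as.integer(seed),
    plan = plan
  ), class = "cohort_config")
}

plan_to_dict <- function(plan) {
  bind_rows(
    tibble(name = "participant_id", theme = NA_character_,
           vtype = "categorical", levels = NA_character_, role = "id"),
    tibble(name = plan$name, theme = plan$theme, vtype = plan$vtype,
           levels = map_chr(plan$levels,
                            function(l) if (is.null(l)) NA_character_ else join_levels(l)),
           role = plan$role)
  )
}

#' Generate the baseline survey table
#'
#' Draws one latent standard-normal factor per theme and per participant;
#' each variable loads on its theme factor with correlation
#' `within_theme_correlation`, then is either rescaled (continuous) or
#' thresholded at normal quantiles to match its level probabilities
#' (categorical). Item missingness is injected completely at random at a
#' per-variable rate drawn from `missing_rate_range`.
#'
#' @param config A [cohort_config()].
#' @return A list with `data` and `dict` tibbles (no wave columns yet) and
#'   `missing_rates`, the realised per-variable missingness probabilities.
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- config$plan
  n <- config$n_participants
  rho <- config$within_theme_correlation
  with_rng(config$seed, {
    factors <- matrix(rnorm(n * length(AW_THEMES)), nrow = n,
                      dimnames = list(NULL, AW_THEMES))
    miss_rates <- runif(nrow(plan), config$missing_rate_range[1],
                        config$missing_rate_range[2])
    names(miss_rates) <- plan$name
    cols <- vector("list", nrow(plan))
    names(cols) <- plan$name
    for (i in seq_len(nrow(plan))) {
      z <- sqrt(rho) * factors[, plan$theme[i]] + sqrt(1 - rho) * rnorm(n)
      if (plan$vtype[i] == "continuous") {
        x <- plan$mean[i] + plan$sd[i] * z
      } else {
        probs <- plan$probs[[i]]
        cuts <- qnorm(cumsum(probs)[-length(probs)])
        x <- plan$levels[[i]][findInterval(z, cuts) + 1L]
      }
      miss <- runif(n) < miss_rates[i]
      x[miss] <- NA
      cols[[i]] <- x
    }
    data <- bind_cols(
      tibble(participant_id = sprintf("P%05d", seq_len(n))),
      as_tibble(cols)
    )
    list(data = data, dict = plan_to_dict(plan), missing_rates = miss_rates)
  })
}

# Per-participant log-odds contribution of the true dropout model
# (intercept excluded). Continuous variables enter per observed-sample SD;
# missing cells contribute the variable's missing-indicator effect.
dropout_linear_predictor <- function(data, dict, effects) {
  lp <- rep(0, nrow(data))
  for (v in names(effects)) {
    eff <- effects[[v]]
    x <- data[[v]]
    miss <- is.na(x)
    if (dict_vtype(dict, v) == "continuous") {
      z <- rep(0, length(x))
      obs <- x[!miss]
      z[!miss] <- (obs - mean(obs)) / sd(obs)
      if (!is.null(eff$steps)) {
        # piecewise-constant risk over brackets of the standardized value
        breaks <- eff$breaks %||% qnorm(seq_len(length(eff$steps) - 1) /
                                          length(eff$steps))
        contrib <- eff$steps[findInterval(z, breaks) + 1L]
        contrib[miss] <- 0
        lp <- lp + contrib
      } else {
        lp <- lp + eff$beta * z
      }
    } else {
      contrib <- unname(eff$levels[match(x, names(eff$levels))])
      contrib[is.na(contrib)] <- 0
      lp <- lp + contrib
    }
    if (!is.null(eff$missing)) lp <- lp + eff$missing * miss
  }
  lp
}

# Solve mean(at_risk * plogis(c + lp)) = target for the intercept c.
calibrate_intercept <- function(lp, at_risk, target, tol = 1e-4) {
  f <- function(c) mean(at_risk * plogis(c + lp)) - target
  if (target <= 0 || target >= 1 || f(35) < 0 || f(-35) > 0) {
    abort(paste0("Continuation target ", target,
                 " is unreachable for this cohort."), class = "aw_config_error")
  }
  lo <- -35; hi <- 35
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol * 1e-2) return(mid)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate wave participation
#'
#' Participation at each wave is Bernoulli with logit equal to the true
#' dropout model's linear predictor plus a per-wave intercept found by
#' bisection so the *expected marginal* continuation rate matches the wave's
#' target (tolerance 1e-4). With `monotone = TRUE`, a participant lost at one
#' wave has indicator 0 at all later waves and the intercepts calibrate the
#' conditional rate so the marginal target is still met in expectation.
#'
#' @param data,dict Baseline cohort tibbles from [generate_baseline()].
#' @param effects True dropout model (see [default_dropout_effects()]).
#' @param wave_targets Named marginal continuation targets.
#' @param monotone Enforce monotone attrition (default `TRUE`).
#' @param seed Integer seed for the Bernoulli draws.
#' @return A list: `data` with `wave_<label>_participation` columns appended,
#'   `dict` with matching wave rows, and `true_model` (effects, per-wave
#'   intercepts, targets, and the realised linear predictor).
#' @export
simulate_participation <- function(data, dict, effects, wave_targets,
                                   monotone = TRUE, seed = 1L) {
  lp <- dropout_linear_predictor(data, dict, effects)
  n <- nrow(data)
  intercepts <- numeric(length(wave_targets))
  names(intercepts) <- names(wave_targets)
  with_rng(seed, {
    prev <- rep(1L, n)
    for (w in names(wave_targets)) {
      at_risk <- if (monotone) prev else rep(1L, n)
      icpt <- calibrate_intercept(lp, at_risk, wave_targets[[w]])
      intercepts[[w]] <- icpt
      ind <- at_risk * rbinom(n, 1L, plogis(icpt + lp))
      data[[wave_column(w)]] <- as.integer(ind)
      prev <- ind
    }
  })
  wave_rows <- tibble(name = wave_column(names(wave_targets)),
                      theme = NA_character_, vtype = "categorical",
                      levels = NA_character_, role = "wave")
  dict <- bind_rows(dict[dict$role != "wave", ], wave_rows)
  list(data = data, dict = dict,
       true_model = list(effects = effects, intercepts = intercepts,
                         targets = wave_targets, linear_predictor = lp))
}

#' Generate a complete synthetic cohort
#'
#' Runs [generate_baseline()] then [simulate_participation()] under one
#' config; the participation draws use `config$seed + 1` so the two stages can
#' be reproduced independently.
#'
#' @param config A [cohort_config()].
#' @return A list with `data`, `dict`, `true_model` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  base <- generate_baseline(config)
  sim <- simulate_participation(base$data, base$dict, config$dropout_effects,
                                config$wave_targets, monotone = config$monotone,
                                seed = config$seed + 1L)
  list(data = sim$data, dict = sim$dict, true_model = sim$true_model,
       missing_rates = base$missing_rates, config = config)
}
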