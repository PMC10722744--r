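# Shared fixtures and independent oracles for the test suite.

# A small but fully featured generator configuration (keeps the variables
# that carry true dropout signal plus a spread of fillers).
small_allocation <- function() {
  c(sociodemographic = 8L, pregnancy_history = 3L, conception_history = 2L,
    prenatal_care = 2L, lifestyle_health_care = 2L,
    mental_health_social_support = 6L, smoking_drug_alcohol = 3L)
}

small_config <- function(n = 600, seed = 1L,
                         wave_targets = c("3y" = 0.594, "5y" = 0.55), ...) {
  cohort_config(n_participants = n, theme_allocation = small_allocation(),
                wave_targets = wave_targets, seed = seed, ...)
}

# Hand-built 5-participant cohort for I/O and recode tests.
tiny_dict <- function() {
  tibble::tibble(
    name = c("participant_id", "color", "age", "wave_3y_participation"),
    theme = c(NA, "sociodemographic", "sociodemographic", NA),
    vtype = c("categorical", "categorical", "continuous", "categorical"),
    levels = c(NA, "red|green|blue", NA, NA),
    role = c("id", "candidate", "candidate", "wave")
  )
}

tiny_data <- function() {
  tibble::tibble(
    participant_id = paste0("P", 1:5),
    color = c("red", "green", NA, "blue", NA),
    age = c(1, 5, 9, NA, 3),
    wave_3y_participation = c(1L, 0L, 1L, 1L, 0L)
  )
}

# Synthetic logistic cohort with continuous predictors, built directly
# (independent of the package generator) for selection tests.
make_logit_cohort <- function(n, p, betas = numeric(p), seed = 1) {
  stopifnot(length(betas) == p)
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  nm <- sprintf("x%02d", seq_len(p))
  colnames(x) <- nm
  y <- rbinom(n, 1, plogis(drop(x %*% betas)))
  data <- tibble::as_tibble(as.data.frame(x))
  data$participant_id <- sprintf("P%05d", seq_len(n))
  data$wave_3y_participation <- y
  dict <- dplyr::bind_rows(
    tibble::tibble(name = "participant_id", theme = NA_character_,
                   vtype = "categorical", levels = NA_character_, role = "id"),
    tibble::tibble(name = nm, theme = "sociodemographic",
                   vtype = "continuous", levels = NA_character_,
                   role = "candidate"),
    tibble::tibble(name = "wave_3y_participation", theme = NA_character_,
                   vtype = "categorical", levels = NA_character_,
                   role = "wave")
  )
  list(data = data[, c("participant_id", nm, "wave_3y_participation")],
       dict = dict)
}

# --- Independent oracles ----------------------------------------------------

# AUC by brute-force enumeration of case-control pairs (ties count 1/2).
oracle_auc_pairs <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) {
    total <- total + sum(a > controls) + 0.5 * sum(a == controls)
  }
  total / (length(cases) * length(controls))
}

# AUC as the trapezoidal area under the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0)
  sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
}

# Fast rank-based AUC used inside the bootstrap oracle.
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(rank(scores)[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Direct-formula standardized differences (percent), written independently
# of the package implementation.
oracle_sd_cont <- function(x, group, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- !is.na(x)
  x <- x[ok]; group <- group[ok]; w <- w[ok]
  wm <- function(x, w) sum(w * x) / sum(w)
  wv <- function(x, w) {
    m <- wm(x, w)
    (sum(w) / (sum(w)^2 - sum(w^2))) * sum(w * (x - m)^2)
  }
  m1 <- wm(x[group == 1], w[group == 1]); m0 <- wm(x[group == 0], w[group == 0])
  v1 <- wv(x[group == 1], w[group == 1]); v0 <- wv(x[group == 0], w[group == 0])
  100 * abs(m1 - m0) / sqrt((v1 + v0) / 2)
}

oracle_sd_cat <- function(x, group, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- !is.na(x)
  x <- x[ok]; group <- group[ok]; w <- w[ok]
  wm <- function(x, w) sum(w * x) / sum(w)
  d <- 0
  for (l in unique(x)) {
    p1 <- wm(x[group == 1] == l, w[group == 1])
    p0 <- wm(x[group == 0] == l, w[group == 0])
    den <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    if (den > 0) d <- max(d, abs(p1 - p0) / den)
  }
  100 * d
}
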