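---
title: "Developing and assessing non-response weights for cohort attrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and assessing non-response weights for cohort attrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the estimand

A longitudinal cohort recruits a baseline sample and re-surveys it at later
waves; participants who stop responding are *lost to follow-up*. If dropout
depends on baseline characteristics, analyses restricted to wave-k
responders describe a population that has drifted away from the one
recruited. Inverse-probability-of-participation weighting addresses this by
modelling, from baseline information only, each participant's probability
`p_hat_i` of continuing at a wave and weighting responders by
`sw_i = p_bar / p_hat_i`, where `p_bar` is the marginal continuation
proportion. The numerator stabilizes the weights: they keep the balancing
property of `1 / p_hat_i` but average about 1 over responders and have a
fraction `p_bar^2` of the unstabilized variance. The estimand the weights
restore is the *baseline* cohort.

The key assumption is sequential ignorability at the wave level: given the
modelled baseline covariates, continuation is independent of everything else
the analysis cares about. Weights cannot repair dropout driven by
unmeasured post-baseline events. A second, practical assumption is that the
participation model is approximately correctly specified; the balance
diagnostics below are the empirical check of both.

## Data model

A cohort is two tibbles. The data table holds one row per participant: an
opaque id, baseline variables (categorical as character, continuous as
numeric, `NA` for item missingness) and one `wave_<label>_participation`
0/1 column per wave. The dictionary describes each column: one of seven
context themes, type, ordered levels, and a role (`candidate`,
`demographic` — a candidate that also enters the balance panel —, `id`, or
`wave`). CSV round-trips write missing cells as empty strings and accept
both empty and the literal `NA` on read.

Two preparation recodes precede modelling, mirroring how attrition models
are usually built on mostly-categorical survey data:

* `categorize_continuous()` cuts continuous variables at fixed cutpoints
  (default: observed quintiles, user-overridable per variable). Intervals
  are left-closed/right-open with the last interval right-closed, so a value
  equal to a cutpoint joins the upper interval. Quintiles were chosen as the
  default because they keep ~20% of the sample per cell regardless of the
  variable's shape; any substantive set of clinical cutpoints can be passed
  instead.
* `recode_missing_as_category()` turns `NA` in a categorical variable into
  an explicit `missing` level, appended only where missingness actually
  occurred. This keeps every participant in the model and lets missingness
  itself predict dropout, at the price of categorizing continuous variables.

## The synthetic cohort generator

The motivating data are restricted, so `simulate_cohort()` generates a
cohort with the structure the analysis relies on. Defaults:

* `n_participants = 3351`, `n = 127` baseline variables allocated over the
  seven themes (30/18/15/15/17/17/15), a mix of 2–6-level categoricals and
  continuous variables. Named variables (education, income, home ownership,
  maternal age, ...) give the dictionary recognisable analogues; 15 of them
  carry the `demographic` role and form the default balance panel.
* Within-theme dependence: every variable loads on a shared latent normal
  theme factor with pairwise correlation 0.25 — enough that unselected
  demographics co-move with true dropout drivers, as real survey blocks do,
  without making theme screens ill-conditioned.
* Item missingness: per-variable rates drawn uniformly from 0–4.4%,
  injected completely at random.
* Dropout: a sparse logistic model on five baseline variables (education,
  home ownership, maternal age, smoking history, anxiety symptoms), each
  missing cell contributing a dedicated missing-indicator effect (−0.2).
  The maternal-age effect is piecewise-constant over quintile brackets of
  the standardized value, so a participation model built on the package's
  own quintile categorization is correctly specified — the generator tests
  the pipeline, not the pipeline's discretization error. Effect magnitudes
  were calibrated once so the *unweighted* maximum absolute standardized
  difference at the first wave averages ~29% (band 25–30%) at n = 3,351,
  the regime where weighting has visible work to do, and were frozen.
* Waves: four labels (3y/5y/8y/covid) with marginal continuation targets
  0.594/0.55/0.50/0.45. The first matches the motivating cohort; the later
  three are plausible placeholders for a maturing cohort and are
  config-overridable. Attrition is monotone by default (a non-attender is
  treated as lost); returning participants can be simulated with
  `monotone = FALSE`. Per-wave intercepts are found by bisection so the
  expected marginal rate hits its target to 1e-4.

What the generator does *not* emulate: realistic marginal distributions of
specific survey instruments, non-random (value-dependent) missingness,
twins/multiple births, or wave-specific administrative disruptions. Passing
tests therefore demonstrate that the machinery recovers a known mechanism
under clean conditions — not that any particular real cohort satisfies the
ignorability assumption.

The true model (effects, calibrated intercepts, linear predictor) is
returned verbatim, which is what makes parameter-recovery and
selection-stability tests possible.

## Variable selection

**A priori arm.** `apriori_select()` validates a curated list (default: 18
variables spanning all themes) and returns it verbatim — deliberately no
data-driven filtering, so the arm reflects pure subject-matter choice.

**LASSO arm.** Within each theme:

1. Candidates are dummy-encoded (first dictionary level as reference) and
   standardized to unit variance, so "largest coefficient" is comparable
   across variables; `cv.glmnet` (binomial deviance, `alpha = 1`) picks the
   penalty minimizing mean 10-fold cross-validated deviance. Folds are
   stratified by outcome and assigned deterministically from a seed.
   `lambda.min` rather than the 1-SE rule: the screen's job is sensitivity,
   and the forward gate and the final combined LASSO provide the
   parsimony pressure.
2. Variables are scored by the maximum absolute level coefficient (a
   categorical variable with one influential level is kept whole) and
   ranked; zero scores drop out, ties break by dictionary order.
3. The theme model starts from the top three ranked variables and adds the
   next-ranked one at a time. After each addition the new model's AUROC is
   compared with the previous model's by the paired DeLong test; the first
   addition with two-sided p > 0.05 stops the walk, and that failing
   variable is *excluded*. ("Include-and-stop" is an equally defensible
   reading of a ROC-gated forward rule; exclusion was chosen because the
   gate is evidence the variable did not improve discrimination. The
   threshold is the `alpha` argument.) The whole walk is recorded in a
   `selection_trace`.
4. The pooled theme winners enter one more cross-validated LASSO — with a
   freshly tuned penalty, since the pooled design has different correlation
   structure than any theme — and variables with any non-zero level
   coefficient are fit by *unpenalized* logistic regression to give the
   final participation model. If everything is zeroed, an intercept-only
   model is returned with a warning.

Two honesty notes. The AUROC gate is computed on the training data, so the
traced AUROCs are optimistic and early stopping is anti-conservative; the
gate's test is pluggable in principle (any paired comparison of correlated
ROC curves), DeLong being the default. And because selection is data-driven,
the final model's coefficients are post-selection estimates — fine for
weighting, not for inference on the selection variables themselves.

## Assessment

* `auroc()` — the Mann–Whitney probability that a random continuer outscores
  a random drop-out (ties count one half), with a DeLong-variance normal CI
  clipped to [0, 1]. Plain rather than logit-scale CIs, matching how such
  models are conventionally reported.
* `delong_paired_test()` — two-sided z-test of the AUC difference of two
  score vectors on the same participants using DeLong structural
  components; when the variance of the difference is zero and the AUCs are
  equal (self-comparison) it returns z = 0, p = 1.
* `hosmer_lemeshow()` — observations binned by quantiles of predicted risk
  (default 10), ties going to the lower bin; bins emptied by ties or with
  degenerate expected counts merge into a neighbour with a warning;
  `df = effective bins − 2`, so the canonical 10-bin test has 8 df.
* `mean_calibration()` — average predicted risk vs observed rate; equal by
  the score equations for an ML logistic fit with intercept evaluated on
  its training data, which the tests assert exactly.
* `calibration_curve()` — loess (span 0.75 by default) of outcome on
  predicted risk over a grid, returned with the ideal diagonal. The span
  only affects plots, never selection or weighting decisions; constant
  predictions yield a single-point curve with a warning.

## Weights

`predict_probabilities()` applies the inverse link for *all* baseline
participants (levels unseen at fit time map to the reference with a
warning, which matters for later-wave re-fits). `stabilized_weights()` uses
the marginal continuation proportion as numerator — the simplest valid
stabilizer; a conditional numerator would change the estimand. Predicted
probabilities of exactly 0 are an error (infinite weight — the signature of
a separated fit; the package then falls back to a ridge-stabilized fit with
a small L2 penalty and says so); probabilities of exactly 1 are admitted
because saturated strata produce them legitimately with finite weights.

`truncate_weights()` clamps to the 0.5th/99.5th empirical percentiles by
default; `low_pct = 0` gives upper-only truncation. The percentile bounds
use linear-interpolation quantiles (type 7) by default; because the count
of altered weights at n ≈ 3,000 is sensitive to the convention, `qtype` is
exposed — type 1 (inverse CDF) additionally makes re-truncation exactly
idempotent, while type 7 is idempotent only up to the interpolation step
beneath the clamped mass.

`refit_for_wave()` keeps the selected variable set and re-estimates
coefficients against each later wave's indicator, re-running the whole
weight pipeline — one selection, many waves.

## Balance diagnostics

Standardized differences compare continuers and drop-outs on the raw
baseline values (complete cases per variable): for continuous variables the
mean difference over the pooled within-group SD; for categorical variables
each level is dichotomized and the variable scores the maximum absolute
level-wise difference (conservative; a Mahalanobis-style multivariate
summary is out of scope). Everything is reported as |d| × 100% against the
conventional 10% threshold.

For the *weighted* comparison the default gives continuers their truncated
stabilized weights `p_bar / p_hat` and drop-outs the complementary inverse
weights `(1 − p_bar) / (1 − p_hat)`, so both groups are reweighted toward
the baseline distribution. This is the scheme under which a correctly
specified model drives the difference to zero — exactly so for a saturated
model on a discrete covariate, which the tests assert — and is what
propensity-style balance checkers effectively do. Weighting only the
responders and comparing them to unweighted drop-outs (available via
`dropout_weighting = "none"`) cannot reach balance even with perfect
weights: reweighted continuers approximate the baseline mixture, which
still differs from the drop-out stratum by roughly `p_bar` times the raw
gap. A third option, `compare = "baseline"`, compares weighted continuers
with the full baseline sample — the most direct check of the estimand, and
mechanically tighter because the groups overlap.

One caveat the package cannot remove: at n ≈ 3,351 a single
continuers-vs-drop-outs standardized difference has a sampling SE of about
3.5 percentage points even under a perfect model, so the maximum over 15
variables and 4 waves hovers near 8% and occasionally crosses 10% by chance
alone. A crossing on one variable-wave in an otherwise flat profile is
noise, not model failure; the profile plot (`plot_multiwave_balance()`) is
the right diagnostic, not the single max.

## Pipeline, determinism, numerics

`run_pipeline()` chains the stages for both arms and all waves, writing
each stage's artifact (models, traces, assessments, weights, balance
tables, manifest with config hash and seed) so stages are independently
re-runnable from serialized outputs. One global seed fans out by fixed
offsets (generator: `seed`; participation draws: `seed + 1`; per-theme CV
folds: `seed + theme index`; combined LASSO: `+100`; pipeline selection:
`+200`), making every artifact reproducible in isolation.

Numerical choices collected in one place: intercept calibration by
bisection on [−35, 35] to 1e-4 on the expected rate; glm fits falling back
to a ridge-stabilized fit (L2, λ = 1e-3) on separation or non-convergence;
constant predictor columns dropped with a warning; Hosmer–Lemeshow bins
merged as above; zero pooled variance in a standardized difference returns
0 when the group means agree and errors otherwise; empty-winner and
all-zero LASSO cases degrade to intercept-only models with warnings rather
than failing.

## Problem sizes used by the test suite

The suite exercises the full study scale where the property demands it
(n = 3,351 with 127 variables for selection stability across 25 seeds,
n = 50,000 for coefficient recovery within 3 SE) and smaller cohorts
(n = 300–2,500, ~26 variables) where the property is scale-free, keeping
the default run to a few minutes. These sizes are package choices made to
match each property's statistical resolution.

## Limitations

Single-wave weights only — no cumulative products of per-wave censoring
weights; no multiple imputation or comparison against it; no
exposure-outcome modelling with the weights (they are exported for use in
any weighted analysis); no elastic-net/group-LASSO variants or
interaction-term search; the ROC gate's in-sample optimism noted above.
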