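#' One-command pipeline
#'
#' Orchestrates simulate -> prepare -> select -> assess -> weight -> balance
#' as a single reproducible run with serialized per-stage artifacts. A single
#' global seed fans out to per-stage seeds by fixed offsets, so any stage can
#' be reproduced in isolation; re-running with the same config and seed is
#' bit-identical for all deterministic artifacts.
#'
#' @name pipeline
NULL

model_as_list <- function(model) {
  list(method = model$method, wave = model$wave,
       variables = as.list(model$variables),
       intercept = model$intercept,
       ridge_stabilized = model$ridge,
       coefficients = lapply(seq_len(nrow(model$coefficients)), function(i) {
         r <- model$coefficients[i, ]
         list(column = r$column, variable = r$variable,
              level = r$level, estimate = r$estimate)
       }))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  path
}

#' Run the full weighting pipeline
#'
#' Generates (or accepts) a cohort, prepares it, runs both selection arms at
#' the first wave, assesses discrimination and calibration, computes
#' truncated stabilized weights, re-fits each selected model at every later
#' wave, and writes balance diagnostics plus a manifest to `out_dir`.
#'
#' @param config A [cohort_config()] describing the synthetic scenario.
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output and just returns the results.
#' @param methods Selection arms to run: subset of `c("apriori", "lasso")`.
#' @param waves Wave labels to develop weights for; default all simulated
#'   waves (selection happens at the first).
#' @param alpha Forward-selection DeLong threshold.
#' @param k_folds Cross-validation folds for the LASSO screens.
#' @param low_pct,high_pct Weight-truncation percentiles.
#' @param demographic Balance panel; default the `demographic`-role
#'   variables.
#' @param curated Curated list for the a priori arm; default the
#'   18-variable list restricted to variables present in the dictionary.
#' @param seed Global seed; default `config$seed`. Stage seeds are derived
#'   by fixed offsets (simulation `seed`, selection `seed + 200`).
#' @param cohort Optional pre-simulated cohort (a list with `data`, `dict`)
#'   to use instead of simulating from `config`.
#' @return Invisibly, a list of class `"pipeline_run"`: `cohort`,
#'   `prepared`, per-method `models`, `assessments`, `weights` (per wave),
#'   `balance` (per wave `"balance_report"`), `multiwave`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         methods = c("apriori", "lasso"), waves = NULL,
                         alpha = 0.05, k_folds = 10, low_pct = 0.5,
                         high_pct = 99.5, demographic = NULL,
                         curated = NULL, seed = NULL, cohort = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  seed <- as.integer(seed %||% config$seed)
  log_lines <- character()
  stage <- function(name, code) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                      " stage: ", name))
    tryCatch(code, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "aw_pipeline_error")
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit_json <- function(x, name) {
    if (!is.null(out_dir)) write_json_artifact(x, file.path(out_dir, name))
  }
  emit_csv <- function(x, name) {
    if (!is.null(out_dir)) readr::write_csv(x, file.path(out_dir, name), na = "")
  }

  sim <- stage("simulate", {
    if (is.null(cohort)) {
      cfg <- config
      cfg$seed <- seed
      simulate_cohort(cfg)
    } else cohort
  })
  if (!is.null(out_dir) && is.null(cohort)) {
    write_cohort(sim$data, sim$dict, file.path(out_dir, "cohort.csv"),
                 file.path(out_dir, "dictionary.csv"))
    emit_json(list(effects = sim$true_model$effects,
                   intercepts = as.list(sim$true_model$intercepts),
                   targets = as.list(sim$true_model$targets)),
              "true_model.json")
  }
  waves <- waves %||% wave_labels(sim$dict)
  first_wave <- waves[1]

  prep <- stage("prepare", prepare_cohort(sim$data, sim$dict))

  results <- list(cohort = sim, prepared = prep, models = list(),
                  assessments = list(), weights = list(), balance = list(),
                  multiwave = list(), selection = list())

  for (m in methods) {
    sel <- stage(paste0("select_", m), {
      if (m == "apriori") {
        cur <- curated %||% intersect(default_apriori_variables(),
                                      prep$dict$name)
        list(model = apriori_model(prep$data, prep$dict, first_wave,
                                   curated = cur))
      } else {
        select_variables_lasso(prep$data, prep$dict, first_wave,
                               alpha = alpha, k_folds = k_folds,
                               seed = seed + 200L)
      }
    })
    results$selection[[m]] <- sel
    emit_json(model_as_list(sel$model), paste0("model_", m, "_", first_wave,
                                               ".json"))
    if (m == "lasso" && !is.null(out_dir)) {
      traces <- bind_rows(lapply(names(sel$traces), function(th) {
        sel$traces[[th]]$trace |> mutate(theme = th, .before = 1)
      }))
      emit_csv(traces, "selection_trace_lasso.csv")
    }

    for (w in waves) {
      fitted <- stage(paste0("fit_", m, "_", w), {
        if (w == first_wave) {
          list(model = sel$model,
               weights = compute_weights(sel$model, prep$data,
                                         low_pct = low_pct,
                                         high_pct = high_pct))
        } else {
          refit_for_wave(sel$model, prep$data, prep$dict, w,
                         low_pct = low_pct, high_pct = high_pct)
        }
      })
      results$models[[m]][[w]] <- fitted$model
      results$weights[[m]][[w]] <- fitted$weights
      assessment <- stage(paste0("assess_", m, "_", w),
                          assess_model(fitted$model, prep$data, prep$dict,
                                       wave = w))
      results$assessments[[m]][[w]] <- assessment
      emit_json(c(as.list(glance.model_assessment(assessment)),
                  list(method = m)), paste0("assessment_", m, "_", w, ".json"))
      emit_csv(as_tibble(fitted$weights), paste0("weights_", m, "_", w, ".csv"))
      emit_json(as.list(weight_summary(fitted$weights)),
                paste0("weight_summary_", m, "_", w, ".json"))
    }
  }

  for (w in waves) {
    ws <- lapply(results$weights, function(per_wave) per_wave[[w]])
    bal <- stage(paste0("balance_", w),
                 balance_table(sim$data, sim$dict, w, weight_sets = ws,
                               demographic = demographic))
    results$balance[[w]] <- bal
    emit_csv(as_tibble(bal), paste0("balance_", w, ".csv"))
  }
  long <- bind_rows(lapply(waves, function(w) {
    tidy.balance_report(results$balance[[w]]) |> mutate(wave = w, .before = 1)
  }))
  results$multiwave <- long
  emit_csv(long, "balance_multiwave.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("attriweight")),
    r_version = R.version.string,
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "plan")]),
    methods = methods,
    waves = waves,
    n_participants = nrow(sim$data),
    log = log_lines
  )
  results$manifest <- manifest
  emit_json(manifest, "manifest.json")
  class(results) <- "pipeline_run"
  invisible(results)
}
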