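#' Variable dictionaries and cohort tables
#'
#' A cohort is represented by two tibbles: a *data* table with one row per
#' participant (an opaque `participant_id`, one column per baseline variable,
#' and one `wave_<label>_participation` indicator column per follow-up wave),
#' and a *dictionary* with one row per column of the data table describing its
#' theme, type, levels and role.
#'
#' Dictionary columns:
#' \describe{
#'   \item{name}{column name in the data table.}
#'   \item{theme}{one of the seven context themes (see [aw_themes()]); `NA`
#'     for `id` and `wave` roles.}
#'   \item{vtype}{`"categorical"` or `"continuous"`.}
#'   \item{levels}{`|`-separated ordered level labels (categorical only).}
#'   \item{role}{`"candidate"`, `"demographic"` (a candidate that also enters
#'     the balance table), `"id"`, or `"wave"`.}
#' }
#'
#' Missing baseline values are `NA` in memory and empty cells (or the literal
#' token `NA`, accepted on read) in delimited files. Wave indicators must be
#' 0/1 with no missingness.
#'
#' @name cohort-data-model
NULL

#' The seven context themes
#'
#' Baseline variables are grouped into seven subject-matter themes
#' (sociodemographic characteristics, pregnancy history, conception history,
#' prenatal care, lifestyle and health-care use during pregnancy, mental
#' health/social support, and smoking/drug/alcohol consumption); LASSO
#' screening runs separately within each theme.
#'
#' @return Character vector of the seven theme labels.
#' @export
aw_themes <- function() AW_THEMES

split_levels <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, "|", fixed = TRUE)[[1]]
}

join_levels <- function(levels) paste(levels, collapse = "|")

dict_levels <- function(dict, variable) {
  split_levels(dict$levels[match(variable, dict$name)])
}

dict_vtype <- function(dict, variable) {
  dict$vtype[match(variable, dict$name)]
}

#' Candidate variable names in a dictionary
#'
#' @param dict A variable dictionary tibble.
#' @param demographic_only If `TRUE`, only variables with role
#'   `"demographic"`.
#' @return Character vector of variable names (roles `candidate` and
#'   `demographic`).
#' @export
candidate_variables <- function(dict, demographic_only = FALSE) {
  roles <- if (demographic_only) "demographic" else c("candidate", "demographic")
  dict$name[dict$role %in% roles]
}

#' Wave labels declared in a dictionary
#'
#' @param dict A variable dictionary tibble.
#' @return Character vector of wave labels, in dictionary order.
#' @export
wave_labels <- function(dict) {
  cols <- dict$name[dict$role == "wave"]
  sub("^wave_(.*)_participation$", "\\1", cols)
}

wave_column <- function(wave) paste0("wave_", wave, "_participation")

validate_dictionary <- function(dict) {
  required <- c("name", "theme", "vtype", "levels", "role")
  missing_cols <- setdiff(required, names(dict))
  if (length(missing_cols) > 0) {
    abort(paste0("Dictionary is missing column(s): ",
                 paste(missing_cols, collapse = ", ")), class = "aw_schema_error")
  }
  if (anyDuplicated(dict$name)) {
    abort("Dictionary variable names must be unique.", class = "aw_schema_error")
  }
  bad_role <- setdiff(unique(dict$role), AW_ROLES)
  if (length(bad_role) > 0) {
    abort(paste0("Unknown dictionary role(s): ", paste(bad_role, collapse = ", ")),
          class = "aw_schema_error")
  }
  vars <- dict[dict$role %in% c("candidate", "demographic"), ]
  bad_theme <- setdiff(unique(vars$theme), AW_THEMES)
  if (length(bad_theme) > 0) {
    abort(paste0("Variable theme(s) outside the seven-theme set: ",
                 paste(bad_theme, collapse = ", ")), class = "aw_schema_error")
  }
  for (i in seq_len(nrow(vars))) {
    lv <- split_levels(vars$levels[i])
    if (vars$vtype[i] == "categorical" && length(lv) < 2) {
      abort(paste0("Categorical variable '", vars$name[i],
                   "' must declare at least 2 levels."), class = "aw_schema_error")
    }
    if (vars$vtype[i] == "continuous" && length(lv) > 0) {
      abort(paste0("Continuous variable '", vars$name[i],
                   "' must not declare levels."), class = "aw_schema_error")
    }
    if (sum(lv == MISSING_LEVEL) > 1) {
      abort(paste0("Variable '", vars$name[i],
                   "' declares the 'missing' level more than once."),
            class = "aw_schema_error")
    }
  }
  invisible(dict)
}

#' Validate a cohort table against its dictionary
#'
#' Checks that participant ids are unique, every data column is declared in
#' the dictionary, categorical cells lie in their declared levels (or are
#' missing), continuous columns are numeric, and wave indicators are complete
#' 0/1 vectors.
#'
#' @param data Cohort data tibble.
#' @param dict Variable dictionary tibble.
#' @return `data`, invisibly. Errors (classes `aw_schema_error`,
#'   `aw_validation_error`) describe the offending column and rows.
#' @export
validate_cohort <- function(data, dict) {
  validate_dictionary(dict)
  id_col <- dict$name[dict$role == "id"]
  if (length(id_col) != 1 || !id_col %in% names(data)) {
    abort("Dictionary must declare exactly one 'id' column present in the data.",
          class = "aw_schema_error")
  }
  if (anyDuplicated(data[[id_col]])) {
    abort("participant ids must be unique.", class = "aw_validation_error")
  }
  undeclared <- setdiff(names(data), dict$name)
  if (length(undeclared) > 0) {
    abort(paste0("Data column(s) absent from the dictionary: ",
                 paste(undeclared, collapse = ", ")), class = "aw_schema_error")
  }
  for (v in intersect(dict$name[dict$role %in% c("candidate", "demographic")],
                      names(data))) {
    vt <- dict_vtype(dict, v)
    x <- data[[v]]
    if (vt == "continuous") {
      if (!is.numeric(x)) {
        abort(paste0("Continuous variable '", v, "' is not numeric."),
              class = "aw_validation_error")
      }
    } else {
      lv <- dict_levels(dict, v)
      bad <- which(!is.na(x) & !(x %in% lv))
      if (length(bad) > 0) {
        abort(paste0("Variable '", v, "' has value(s) outside declared levels ",
                     "at row(s) ", paste(head(bad, 5), collapse = ", "),
                     if (length(bad) > 5) " ..." else "",
                     " (e.g. '", x[bad[1]], "')."),
              class = "aw_validation_error")
      }
    }
  }
  for (w in intersect(dict$name[dict$role == "wave"], names(data))) {
    x <- data[[w]]
    if (anyNA(x) || !all(x %in% c(0, 1))) {
      abort(paste0("Wave indicator '", w, "' must be 0/1 with no missing values."),
            class = "aw_validation_error")
    }
  }
  invisible(data)
}

#' Read a cohort table and variable dictionary from delimited files
#'
#' Empty cells and the literal token `NA` are both read as missing.
#'
#' @param table_path Path to the cohort CSV (one participant per row).
#' @param dictionary_path Path to the dictionary CSV (columns `name`, `theme`,
#'   `vtype`, `levels`, `role`).
#' @return A list with elements `data` and `dict`, both tibbles, validated
#'   against each other.
#' @export
read_cohort <- function(table_path, dictionary_path) {
  for (p in c(table_path, dictionary_path)) {
    if (!file.exists(p)) abort(paste0("File not found: ", p))
  }
  dict <- readr::read_csv(dictionary_path, col_types = readr::cols(
    .default = readr::col_character()))
  validate_dictionary(dict)
  types <- setNames(rep("c", nrow(dict)), dict$name)
  types[dict$vtype == "continuous" & dict$role %in% c("candidate", "demographic")] <- "d"
  types[dict$role == "wave"] <- "i"
  data <- readr::read_csv(table_path,
                          col_types = do.call(readr::cols, as.list(types)),
                          na = c("", "NA"))
  validate_cohort(data, dict)
  list(data = data, dict = dict)
}

#' Write a cohort table and dictionary to delimited files
#'
#' Missing values are written as empty cells.
#'
#' @param data,dict Cohort data and dictionary tibbles.
#' @param table_path,dictionary_path Output CSV paths.
#' @return The input `data`, invisibly.
#' @export
write_cohort <- function(data, dict, table_path, dictionary_path) {
  validate_cohort(data, dict)
  readr::write_csv(data, table_path, na = "")
  readr::write_csv(dict, dictionary_path, na = "")
  invisible(data)
}

#' Recode missingness as an explicit category
#'
#' For categorical variables, missing cells become the level `"missing"`; the
#' level is appended to the dictionary entry only where missingness actually
#' occurred. Continuous variables must be categorized first (see
#' [categorize_continuous()]).
#'
#' @param data,dict Cohort data and dictionary tibbles.
#' @param variables Variables to recode; default all categorical candidates.
#' @return A list with the updated `data` and `dict`.
#' @export
recode_missing_as_category <- function(data, dict, variables = NULL) {
  if (is.null(variables)) {
    cand <- candidate_variables(dict)
    variables <- cand[dict_vtype(dict, cand) == "categorical"]
  }
  for (v in variables) {
    if (!v %in% dict$name) {
      abort(paste0("Unknown variable '", v, "'."), class = "aw_schema_error")
    }
    if (dict_vtype(dict, v) != "categorical") {
      abort(paste0("Variable '", v, "' is continuous; recode applies to ",
                   "categorical variables only."), class = "aw_type_error")
    }
    miss <- is.na(data[[v]])
    if (any(miss)) {
      data[[v]][miss] <- MISSING_LEVEL
      lv <- dict_levels(dict, v)
      if (!MISSING_LEVEL %in% lv) {
        dict$levels[dict$name == v] <- join_levels(c(lv, MISSING_LEVEL))
      }
    }
  }
  list(data = data, dict = dict)
}

interval_labels <- function(cutpoints) {
  lo <- c("-Inf", format(cutpoints, trim = TRUE))
  hi <- c(format(cutpoints, trim = TRUE), "Inf")
  close <- c(rep(")", length(cutpoints)), "]")
  paste0("[", lo, ",", hi, close)
}

#' Categorize a continuous variable at fixed cutpoints
#'
#' Intervals are left-closed/right-open (a value equal to a cutpoint falls in
#' the upper interval); the final interval is right-closed. The default
#' cutpoints are the observed quintiles. Missing values stay missing (recode
#' them afterwards with [recode_missing_as_category()]).
#'
#' @param data,dict Cohort data and dictionary tibbles.
#' @param variable Name of a continuous variable.
#' @param cutpoints Strictly increasing numeric breakpoints; default the
#'   0.2/0.4/0.6/0.8 quantiles of the observed values (deduplicated).
#' @return A list with the updated `data` and `dict` (the variable becomes
#'   categorical with `length(cutpoints) + 1` interval levels).
#' @export
categorize_continuous <- function(data, dict, variable, cutpoints = NULL) {
  if (!variable %in% dict$name) {
    abort(paste0("Unknown variable '", variable, "'."), class = "aw_schema_error")
  }
  if (dict_vtype(dict, variable) != "continuous") {
    abort(paste0("Variable '", variable, "' is not continuous."),
          class = "aw_type_error")
  }
  x <- data[[variable]]
  if (is.null(cutpoints)) {
    cutpoints <- unique(unname(quantile(x, probs = c(0.2, 0.4, 0.6, 0.8),
                                        na.rm = TRUE, type = 7)))
  }
  if (length(cutpoints) < 1 || is.unsorted(cutpoints, strictly = TRUE)) {
    abort("cutpoints must be strictly increasing.", class = "aw_argument_error")
  }
  labs <- interval_labels(cutpoints)
  bin <- findInterval(x, cutpoints) + 1L
  out <- ifelse(is.na(x), NA_character_, labs[bin])
  data[[variable]] <- out
  dict$vtype[dict$name == variable] <- "categorical"
  dict$levels[dict$name == variable] <- join_levels(labs)
  list(data = data, dict = dict)
}

#' Prepare a cohort for participation modelling
#'
#' Applies the variable-preparation recodes used throughout: every continuous
#' candidate variable is cut into categories (default: observed quintiles,
#' overridable per variable), then missingness in every categorical candidate
#' is recoded as an explicit `"missing"` level. The result is a fully
#' categorical candidate set with no missing cells.
#'
#' @param data,dict Cohort data and dictionary tibbles.
#' @param cutpoints Optional named list of numeric cutpoint vectors, one entry
#'   per continuous variable to override the quintile default.
#' @return A list with the prepared `data` and `dict`.
#' @export
prepare_cohort <- function(data, dict, cutpoints = list()) {
  validate_cohort(data, dict)
  cand <- candidate_variables(dict)
  cont <- cand[dict_vtype(dict, cand) == "continuous"]
  for (v in cont) {
    res <- categorize_continuous(data, dict, v, cutpoints = cutpoints[[v]])
    data <- res$data
    dict <- res$dict
  }
  recode_missing_as_category(data, dict)
}
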