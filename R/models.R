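#' Construct a logistic prediction model
#'
#' A logistic model is an intercept plus named term coefficients; the
#' predicted probability of the outcome is
#' `1 / (1 + exp(-(intercept + sum(coef * value))))`.
#'
#' @param intercept Real intercept on the logit scale.
#' @param coefficients Named numeric vector of term coefficients; names must
#'   be unique.
#' @param label Short model label.
#' @return An object of class `logistic_model`.
#' @export
logistic_model <- function(intercept, coefficients, label = "custom") {
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept)) {
    stop_pneumorisk("`intercept` must be a single finite number",
                    class = "pneumorisk_input_error")
  }
  if (is.null(names(coefficients)) || any(names(coefficients) == "") ||
      anyDuplicated(names(coefficients))) {
    stop_pneumorisk("`coefficients` must have unique non-empty names",
                    class = "pneumorisk_input_error")
  }
  structure(
    list(intercept = intercept, coefficients = coefficients,
         label = as.character(label)[1]),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> ", x$label, "\n", sep = "")
  cat("  logit(p) =", format(x$intercept))
  for (nm in names(x$coefficients)) {
    co <- x$coefficients[[nm]]
    cat(if (co >= 0) " + " else " - ", format(abs(co)), " * ", nm, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Published prediction equations for pneumonia
#'
#' The two logistic equations for the probability of consolidation on chest
#' X ray in primary-care patients with an acute respiratory tract infection:
#' the clinical model uses absence of runny nose and feeling ill;
#' the CRP-augmented model adds an indicator for CRP > 30 mg/l.
#' Coefficients are the published values, taken at face value.
#'
#' @return A `logistic_model`.
#' @export
published_clinical_model <- function() {
  logistic_model(
    intercept = -4.492,
    coefficients = c(runny_nose_absent = 1.142, feels_ill = 2.550),
    label = "clinical"
  )
}

#' @rdname published_clinical_model
#' @export
published_crp_model <- function() {
  logistic_model(
    intercept = -4.797,
    coefficients = c(runny_nose_absent = 1.230, feels_ill = 2.378,
                     crp_gt_30 = 1.572),
    label = "clinical_crp"
  )
}

#' Look up a published model by name
#'
#' @param name `"clinical"` or `"clinical_crp"`.
#' @return A `logistic_model`.
#' @export
get_published_model <- function(name) {
  switch(as.character(name)[1],
    clinical     = published_clinical_model(),
    clinical_crp = published_crp_model(),
    stop_pneumorisk("unknown model name '", name,
                    "' (expected 'clinical' or 'clinical_crp')",
                    class = "pneumorisk_input_error")
  )
}

#' Serialise a logistic model to JSON
#'
#' Writes the model constants (label, intercept, term/coefficient pairs) in a
#' small JSON representation so other tools can reference the published
#' models by name.
#'
#' @param model A `logistic_model`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to a file.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "logistic_model"))
  obj <- list(
    label = model$label,
    intercept = model$intercept,
    terms = data.frame(predictor = names(model$coefficients),
                       coefficient = unname(model$coefficients))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read a logistic model from its JSON representation
#'
#' @param path Path to a JSON file produced by [model_to_json()].
#' @return A `logistic_model`.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  co <- stats::setNames(obj$terms$coefficient, obj$terms$predictor)
  logistic_model(obj$intercept, co, label = obj$label)
}

# Assemble the covariate columns a model needs from a data frame. The
# crp_gt_30 indicator is derived from crp_mg_per_l (cutoff 30 mg/l, strict
# ">") when not supplied directly.
model_covariates <- function(model, data) {
  needed <- names(model$coefficients)
  out <- list()
  for (nm in needed) {
    if (nm %in% names(data)) {
      out[[nm]] <- as.numeric(data[[nm]])
    } else if (nm == "crp_gt_30" && "crp_mg_per_l" %in% names(data)) {
      out[[nm]] <- biomarker_indicator(data[["crp_mg_per_l"]], 30)
    } else {
      stop_pneumorisk("model term '", nm, "' has no corresponding covariate",
                      class = "pneumorisk_missing_predictor_error")
    }
  }
  as.data.frame(out, optional = TRUE)
}

# raw data fields required to evaluate a model (crp_gt_30 maps back to
# crp_mg_per_l unless supplied directly)
model_required_fields <- function(model, data_names) {
  vapply(names(model$coefficients), function(nm) {
    if (!nm %in% data_names && nm == "crp_gt_30") "crp_mg_per_l" else nm
  }, character(1), USE.NAMES = FALSE)
}

#' Predicted probability from a logistic model
#'
#' Evaluates `1 / (1 + exp(-(intercept + sum(coef * value))))` for each row
#' of `newdata`. Every model term must have a non-missing value; a missing
#' covariate raises an error so the caller can decide how to handle
#' exclusions (see [complete_case_subset()]). For the CRP-augmented published
#' model, the `crp_gt_30` indicator is derived from `crp_mg_per_l` when not
#' supplied.
#'
#' @param model A `logistic_model`.
#' @param newdata Data frame (or named list coercible to one) of covariates.
#' @return Numeric vector of probabilities, strictly inside (0, 1).
#' @export
#' @examples
#' predict_probability(published_clinical_model(),
#'                     data.frame(runny_nose_absent = 0, feels_ill = 0))
predict_probability <- function(model, newdata) {
  stopifnot(inherits(model, "logistic_model"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata, optional = TRUE)
  x <- model_covariates(model, newdata)
  if (anyNA(x)) {
    miss <- names(x)[vapply(x, anyNA, logical(1))]
    stop_pneumorisk("missing value(s) for model term(s): ",
                    paste(miss, collapse = ", "),
                    class = "pneumorisk_missing_predictor_error")
  }
  lp <- model$intercept + as.vector(as.matrix(x) %*% model$coefficients)
  stats::plogis(lp)
}

#' Fit a binary logistic regression by maximum likelihood
#'
#' Fits the outcome on the given predictors over the complete cases of the
#' cohort, via iteratively reweighted least squares ([stats::glm()] with a
#' binomial family). Reports Wald standard errors, odds ratios with 95%
#' confidence intervals (`exp(coef +/- 1.96 se)`) and Wald p-values.
#' (Quasi-)complete separation is detected from non-convergence or a
#' coefficient magnitude above 15 on the logit scale.
#'
#' @param x A `pneumonia_cohort` or a data frame.
#' @param outcome Name of the binary outcome column (default
#'   `"consolidation"`).
#' @param predictors Character vector of predictor column names. The derived
#'   indicator `crp_gt_30` is accepted and computed from `crp_mg_per_l`.
#' @param error_on_separation If `TRUE` (default), separation raises an
#'   error; if `FALSE` the fit is returned with `converged = FALSE` and a
#'   diagnostic message.
#' @return An object of class `fit_result` with elements `model`
#'   (a `logistic_model`), `std_errors`, `odds_ratios`, `or_ci95`
#'   (two-column matrix), `p_values`, `log_likelihood`, `n_used`,
#'   `converged`, `diagnostic`.
#' @export
fit_logistic <- function(x, outcome = "consolidation", predictors,
                         error_on_separation = TRUE) {
  d <- if (inherits(x, "pneumonia_cohort")) cohort_data(x) else as.data.frame(x)
  if (!outcome %in% names(d)) {
    stop_pneumorisk("unknown outcome column '", outcome, "'",
                    class = "pneumorisk_input_error")
  }
  if (length(predictors) < 1) {
    stop_pneumorisk("at least one predictor is required",
                    class = "pneumorisk_input_error")
  }
  # materialise derived indicators
  for (nm in predictors) {
    if (!nm %in% names(d)) {
      if (nm == "crp_gt_30" && "crp_mg_per_l" %in% names(d)) {
        d$crp_gt_30 <- biomarker_indicator(d$crp_mg_per_l, 30)
      } else {
        stop_pneumorisk("unknown predictor column '", nm, "'",
                        class = "pneumorisk_input_error")
      }
    }
  }
  use <- stats::complete.cases(d[, c(outcome, predictors), drop = FALSE])
  dd <- d[use, c(outcome, predictors), drop = FALSE]
  y <- dd[[outcome]]
  if (!is_binary01(y)) {
    stop_pneumorisk("outcome must be binary 0/1", class = "pneumorisk_input_error")
  }
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    stop_pneumorisk("need at least one event and one non-event among complete cases",
                    class = "pneumorisk_input_error")
  }
  for (nm in predictors) {
    if (length(unique(dd[[nm]])) < 2) {
      stop_pneumorisk("predictor '", nm, "' is constant (or all-missing) ",
                      "among complete cases", class = "pneumorisk_input_error")
    }
  }
  form <- stats::reformulate(predictors, response = outcome)
  fit <- suppressWarnings(
    stats::glm(form, data = dd, family = stats::binomial())
  )
  co <- stats::coef(fit)
  separated <- !fit$converged || any(abs(co) > 15)
  if (separated && error_on_separation) {
    stop_pneumorisk("logistic fit did not converge (likely complete or ",
                    "quasi-complete separation); coefficients: ",
                    paste(sprintf("%s=%.2f", names(co), co), collapse = ", "),
                    class = "pneumorisk_separation_error")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  term_names <- names(co)[-1]
  beta <- co[-1]
  se_t <- se[-1]
  ci <- cbind(lower = exp(beta - 1.96 * se_t), upper = exp(beta + 1.96 * se_t))
  rownames(ci) <- term_names
  z <- co / se
  structure(
    list(
      model = logistic_model(unname(co[1]), stats::setNames(unname(beta), term_names),
                             label = paste0("fit:", outcome)),
      std_errors = stats::setNames(unname(se_t), term_names),
      odds_ratios = stats::setNames(exp(unname(beta)), term_names),
      or_ci95 = ci,
      p_values = stats::setNames(2 * stats::pnorm(-abs(unname(z[-1]))), term_names),
      log_likelihood = as.numeric(stats::logLik(fit)),
      null_log_likelihood = as.numeric(stats::logLik(
        stats::glm(stats::reformulate("1", response = outcome),
                   data = dd, family = stats::binomial())
      )),
      n_used = nrow(dd),
      converged = !separated,
      diagnostic = if (separated) "possible (quasi-)complete separation" else NA_character_
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$model$label, " (n = ", x$n_used,
      if (!x$converged) ", NOT CONVERGED" else "", ")\n", sep = "")
  tab <- data.frame(
    coef = x$model$coefficients,
    se = x$std_errors,
    OR = x$odds_ratios,
    ci_low = x$or_ci95[, "lower"],
    ci_high = x$or_ci95[, "upper"],
    p = x$p_values
  )
  print(round(tab, 4))
  cat("intercept:", format(x$model$intercept),
      " logLik:", format(x$log_likelihood), "\n")
  invisible(x)
}

#' Univariate odds ratio via logistic regression
#'
#' Single-predictor convenience wrapper around [fit_logistic()]; for a
#' binary predictor the odds ratio equals the 2x2 cross-product ratio.
#'
#' @inheritParams fit_logistic
#' @param predictor Single predictor column name.
#' @return A `fit_result`.
#' @export
univariate_or <- function(x, outcome = "consolidation", predictor,
                          error_on_separation = TRUE) {
  stopifnot(length(predictor) == 1)
  fit_logistic(x, outcome = outcome, predictors = predictor,
               error_on_separation = error_on_separation)
}

#' CRB-65 severity score
#'
#' One point each for: new-onset confusion; respiratory rate >= 30/min;
#' blood pressure criterion (systolic < 90 mmHg or diastolic <= 60 mmHg,
#' counted once); age >= 65 years. Range 0-4; higher scores imply higher
#' 30-day mortality. All inputs must be non-missing: no partial scores.
#'
#' @param confusion_new_onset Binary (0/1).
#' @param respiratory_rate_per_min Breaths per minute.
#' @param systolic_bp_mmHg,diastolic_bp_mmHg Blood pressure, mmHg.
#' @param age_years Age in years.
#' @return Integer vector of scores in \[0, 4\].
#' @export
#' @examples
#' crb65_score(0, 25, 120, 80, 70)  # 1: only the age criterion
crb65_score <- function(confusion_new_onset, respiratory_rate_per_min,
                        systolic_bp_mmHg, diastolic_bp_mmHg, age_years) {
  args <- list(confusion_new_onset, respiratory_rate_per_min,
               systolic_bp_mmHg, diastolic_bp_mmHg, age_years)
  if (any(vapply(args, anyNA, logical(1)))) {
    stop_pneumorisk("all CRB-65 inputs must be non-missing (no partial scores)",
                    class = "pneumorisk_input_error")
  }
  if (!is_binary01(confusion_new_onset)) {
    stop_pneumorisk("confusion_new_onset must be 0 or 1",
                    class = "pneumorisk_input_error")
  }
  as.integer(
    (confusion_new_onset == 1) +
      (respiratory_rate_per_min >= 30) +
      (systolic_bp_mmHg < 90 | diastolic_bp_mmHg <= 60) +
      (age_years >= 65)
  )
}

#' Guideline CRP decision bands
#'
#' CRP < 20 mg/l can rule out pneumonia with reasonable certainty; CRP
#' > 100 mg/l indicates likely benefit from antibiotic treatment; between
#' 20 and 100 mg/l (inclusive) the decision rests on the clinical picture.
#'
#' @param crp_mg_per_l Non-negative CRP values, mg/l.
#' @return Ordered factor with levels `rule_out < intermediate < treat`.
#' @export
crp_band <- function(crp_mg_per_l) {
  if (any(crp_mg_per_l < 0, na.rm = TRUE)) {
    stop_pneumorisk("CRP values must be non-negative", class = "pneumorisk_input_error")
  }
  band <- ifelse(is.na(crp_mg_per_l), NA_character_,
                 ifelse(crp_mg_per_l < 20, "rule_out",
                        ifelse(crp_mg_per_l > 100, "treat", "intermediate")))
  factor(band, levels = c("rule_out", "intermediate", "treat"), ordered = TRUE)
}

#' Dichotomise a biomarker at a cutoff
#'
#' Returns 1 when the value is strictly greater than the cutoff, 0 otherwise;
#' values exactly at the cutoff score 0 (strict ">", matching the
#' "CRP > 30 mg/l" notation; ties at the cutoff are not addressed by the
#' source convention and are resolved downward here). Missing values
#' propagate as missing indicators.
#'
#' @param value Non-negative biomarker values.
#' @param cutoff Positive cutoff on the same scale.
#' @return Numeric 0/1/NA vector.
#' @export
#' @examples
#' biomarker_indicator(c(45, 30, NA), 30)  # 1 0 NA
biomarker_indicator <- function(value, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop_pneumorisk("`cutoff` must be a single positive number",
                    class = "pneumorisk_input_error")
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop_pneumorisk("biomarker values must be non-negative",
                    class = "pneumorisk_input_error")
  }
  ifelse(is.na(value), NA_real_, as.numeric(value > cutoff))
}
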