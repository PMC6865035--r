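#' Risk-group thresholds
#'
#' Probability cut points for the three predefined diagnostic risk groups:
#' low risk below `low_upper` (default 2.5%), high risk above `high_lower`
#' (default 20%), intermediate in between. The intermediate band is closed on
#' both ends: p equal to a cut point is intermediate ("less than 2.5%" and
#' "above 20%" are strict).
#'
#' @param low_upper Upper bound of the low-risk band (default 0.025).
#' @param high_lower Lower bound of the high-risk band (default 0.20).
#' @return An object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(low_upper = 0.025, high_lower = 0.20) {
  if (!(low_upper > 0 && low_upper < high_lower && high_lower < 1)) {
    stop_pneumorisk("need 0 < low_upper < high_lower < 1",
                    class = "pneumorisk_input_error")
  }
  structure(list(low_upper = low_upper, high_lower = high_lower),
            class = "risk_thresholds")
}

risk_levels <- function() c("low", "intermediate", "high")

#' Assign three-tier risk groups
#'
#' Maps predicted probabilities to the ordered strata
#' `low < intermediate < high` using [risk_thresholds()].
#'
#' @param p Probabilities in \[0, 1\].
#' @param thresholds A `risk_thresholds` (default 2.5% / 20%).
#' @return Ordered factor with levels low, intermediate, high.
#' @export
#' @examples
#' assign_risk_group(c(0.011, 0.31, 0.025))  # low, high, intermediate
assign_risk_group <- function(p, thresholds = risk_thresholds()) {
  stopifnot(inherits(thresholds, "risk_thresholds"))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_pneumorisk("probabilities must be non-missing and within [0, 1]",
                    class = "pneumorisk_input_error")
  }
  g <- ifelse(p < thresholds$low_upper, "low",
              ifelse(p > thresholds$high_lower, "high", "intermediate"))
  factor(g, levels = risk_levels(), ordered = TRUE)
}

#' Stratify a cohort into risk groups under a model
#'
#' Computes each complete-case patient's predicted probability under `model`,
#' assigns risk groups, and summarises group sizes, events and within-group
#' outcome prevalence. Records missing any model covariate (or the outcome)
#' are excluded and counted per field.
#'
#' @param x A `pneumonia_cohort`.
#' @param model A `logistic_model`.
#' @param thresholds A `risk_thresholds`.
#' @return An object of class `risk_stratification`: list with
#'   `assignments` (data frame: patient_id, probability, group, outcome),
#'   `group_counts`, `events_per_group`, `prevalence` (event fraction per
#'   group, `NaN` for empty groups), `n_used`, `n_excluded` (per required
#'   field), `model_label`, `thresholds`.
#' @export
stratify_cohort <- function(x, model, thresholds = risk_thresholds()) {
  stopifnot(inherits(x, "pneumonia_cohort"), inherits(model, "logistic_model"))
  required <- unique(c(model_required_fields(model, names(cohort_data(x))),
                       "consolidation"))
  cc <- complete_case_subset(x, required)
  d <- cohort_data(cc)
  if (nrow(d) == 0) {
    stop_pneumorisk("no complete cases for model '", model$label, "'",
                    class = "pneumorisk_input_error")
  }
  p <- predict_probability(model, d)
  g <- assign_risk_group(p, thresholds)
  counts <- table(g)
  events <- tapply(d$consolidation, g, sum)
  events[is.na(events)] <- 0
  prev <- as.numeric(events) / as.numeric(counts)
  structure(
    list(
      assignments = data.frame(patient_id = d$patient_id, probability = p,
                               group = g, outcome = d$consolidation,
                               stringsAsFactors = FALSE),
      group_counts = stats::setNames(as.integer(counts), risk_levels()),
      events_per_group = stats::setNames(as.integer(events), risk_levels()),
      prevalence = stats::setNames(prev, risk_levels()),
      n_used = nrow(d),
      n_excluded = attr(cc, "exclusions"),
      model_label = model$label,
      thresholds = thresholds
    ),
    class = "risk_stratification"
  )
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat("<risk_stratification> model '", x$model_label, "', n = ", x$n_used,
      " complete cases\n", sep = "")
  tab <- data.frame(
    group = risk_levels(),
    n = x$group_counts,
    events = x$events_per_group,
    prevalence = ifelse(x$group_counts > 0, fmt_percent(x$prevalence), "-")
  )
  print(tab, row.names = FALSE)
  excl <- x$n_excluded[x$n_excluded > 0]
  if (length(excl) > 0) {
    cat("  excluded for missingness: ",
        paste(names(excl), excl, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Fraction of patients in a decisive (low or high) risk group
#'
#' For low- and high-risk patients an antibiotic treatment decision can be
#' made without a chest X ray; this is the share of analysed patients in
#' those two strata.
#'
#' @param x A `risk_stratification` (or a named count vector with entries
#'   low/intermediate/high).
#' @return Fraction in \[0, 1\].
#' @export
decisive_fraction <- function(x) {
  counts <- if (inherits(x, "risk_stratification")) x$group_counts else x
  if (!all(risk_levels() %in% names(counts))) {
    stop_pneumorisk("counts must be named low/intermediate/high",
                    class = "pneumorisk_input_error")
  }
  total <- sum(counts[risk_levels()])
  if (total == 0) {
    stop_pneumorisk("no patients stratified", class = "pneumorisk_input_error")
  }
  unname((counts[["low"]] + counts[["high"]]) / total)
}
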