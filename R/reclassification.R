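#' Build an outcome-stratified reclassification table
#'
#' Cross-tabulates old-model risk groups (rows) against new-model risk
#' groups (columns), separately for patients with the outcome (events) and
#' without (non-events).
#'
#' @param old,new Risk-group assignments for the same patients, in the same
#'   order (factors or character vectors with levels low/intermediate/high).
#' @param outcomes Binary outcome vector (1 = event), same length.
#' @return An object of class `reclassification_table`: 3x3 integer matrices
#'   `events` and `non_events`, plus `n_events` and `n_non_events`.
#' @export
build_reclassification_table <- function(old, new, outcomes) {
  if (length(old) != length(new) || length(old) != length(outcomes)) {
    stop_pneumorisk("`old`, `new` and `outcomes` must have equal lengths",
                    class = "pneumorisk_input_error")
  }
  if (!is_binary01(outcomes) || anyNA(outcomes)) {
    stop_pneumorisk("`outcomes` must be 0/1 with no missing values",
                    class = "pneumorisk_input_error")
  }
  lv <- risk_levels()
  old <- factor(as.character(old), levels = lv, ordered = TRUE)
  new <- factor(as.character(new), levels = lv, ordered = TRUE)
  if (anyNA(old) || anyNA(new)) {
    stop_pneumorisk("risk groups must be low/intermediate/high with no missing values",
                    class = "pneumorisk_input_error")
  }
  xt <- function(keep) {
    m <- table(old = old[keep], new = new[keep])
    matrix(as.integer(m), 3, 3, dimnames = list(old = lv, new = lv))
  }
  structure(
    list(events = xt(outcomes == 1), non_events = xt(outcomes == 0),
         n_events = sum(outcomes == 1), n_non_events = sum(outcomes == 0)),
    class = "reclassification_table"
  )
}

#' @export
print.reclassification_table <- function(x, ...) {
  cat("<reclassification_table> old-model rows x new-model columns\n")
  cat("Events (n = ", x$n_events, "):\n", sep = "")
  print(x$events)
  cat("Non-events (n = ", x$n_non_events, "):\n", sep = "")
  print(x$non_events)
  invisible(x)
}

#' Reclassify a cohort between two models
#'
#' Stratifies the joint complete cases (records with all covariates of both
#' models and the outcome) under the old and the new model and builds the
#' reclassification table.
#'
#' @param x A `pneumonia_cohort`.
#' @param old_model,new_model `logistic_model`s to compare.
#' @param thresholds A `risk_thresholds`.
#' @return List with `table` (a `reclassification_table`), `old`, `new`
#'   (the two `risk_stratification`s on the shared complete cases),
#'   `n_used` and `n_excluded`.
#' @export
reclassify_cohort <- function(x, old_model, new_model,
                              thresholds = risk_thresholds()) {
  stopifnot(inherits(x, "pneumonia_cohort"))
  nm <- names(cohort_data(x))
  required <- unique(c(model_required_fields(old_model, nm),
                       model_required_fields(new_model, nm),
                       "consolidation"))
  cc <- complete_case_subset(x, required)
  if (n_records(cc) == 0) {
    stop_pneumorisk("no records have complete covariates for both models",
                    class = "pneumorisk_input_error")
  }
  old_s <- stratify_cohort(cc, old_model, thresholds)
  new_s <- stratify_cohort(cc, new_model, thresholds)
  tab <- build_reclassification_table(old_s$assignments$group,
                                      new_s$assignments$group,
                                      old_s$assignments$outcome)
  list(table = tab, old = old_s, new = new_s,
       n_used = n_records(cc), n_excluded = attr(cc, "exclusions"))
}

up_down_counts <- function(m) {
  c(up = sum(m[upper.tri(m)]), down = sum(m[lower.tri(m)]))
}

#' Reclassification improvement statistics (ORI and NRI)
#'
#' A move to a higher risk group is correct for a patient with the outcome
#' and incorrect for one without; a move to a lower group is the reverse.
#' The overall reclassification improvement (ORI) subtracts incorrectly from
#' correctly reclassified patients and divides by the total number of
#' analysed patients, weighting every patient equally. The net
#' reclassification improvement (NRI) instead sums the two per-group net
#' fractions, `(up - down)/n_events + (down - up)/n_non_events`, which
#' overweights the smaller outcome group when the groups are unbalanced.
#'
#' @param table A `reclassification_table`.
#' @return An object of class `reclass_summary` with fields
#'   `event_improvement`, `non_event_improvement`, `overall_improvement`,
#'   `nri` (signed fractions), and counts `n_up_events`, `n_down_events`,
#'   `n_up_non_events`, `n_down_non_events`, `n_events`, `n_non_events`.
#' @export
reclassification_summary <- function(table) {
  stopifnot(inherits(table, "reclassification_table"))
  if (table$n_events + table$n_non_events == 0) {
    stop_pneumorisk("empty reclassification table", class = "pneumorisk_input_error")
  }
  if (table$n_events == 0) {
    stop_pneumorisk("no events: event improvement undefined",
                    class = "pneumorisk_input_error")
  }
  if (table$n_non_events == 0) {
    stop_pneumorisk("no non-events: non-event improvement undefined",
                    class = "pneumorisk_input_error")
  }
  ev <- up_down_counts(table$events)
  ne <- up_down_counts(table$non_events)
  event_improvement <- (ev[["up"]] - ev[["down"]]) / table$n_events
  non_event_improvement <- (ne[["down"]] - ne[["up"]]) / table$n_non_events
  overall <- (ev[["up"]] - ev[["down"]] + ne[["down"]] - ne[["up"]]) /
    (table$n_events + table$n_non_events)
  structure(
    list(
      event_improvement = event_improvement,
      non_event_improvement = non_event_improvement,
      overall_improvement = overall,
      nri = event_improvement + non_event_improvement,
      n_up_events = ev[["up"]], n_down_events = ev[["down"]],
      n_up_non_events = ne[["up"]], n_down_non_events = ne[["down"]],
      n_events = table$n_events, n_non_events = table$n_non_events
    ),
    class = "reclass_summary"
  )
}

#' @export
print.reclass_summary <- function(x, ...) {
  cat("<reclass_summary>\n")
  cat("  events:     ", x$n_up_events, " up, ", x$n_down_events, " down of ",
      x$n_events, "  -> ", fmt_percent(x$event_improvement), "\n", sep = "")
  cat("  non-events: ", x$n_up_non_events, " up, ", x$n_down_non_events,
      " down of ", x$n_non_events, "  -> ",
      fmt_percent(x$non_event_improvement), "\n", sep = "")
  cat("  overall reclassification improvement (ORI): ",
      fmt_percent(x$overall_improvement), "\n", sep = "")
  cat("  net reclassification improvement (NRI):     ",
      fmt_percent(x$nri), "\n", sep = "")
  invisible(x)
}

#' Summary of intermediate-to-high reclassification
#'
#' Patients moved from the intermediate to the high risk group are the ones
#' for whom the added biomarker would trigger antibiotic treatment; this
#' summarises that cell of the table.
#'
#' @param table A `reclassification_table`.
#' @return List: `n_moved` (intermediate -> high, both outcomes),
#'   `n_events_moved`, `event_fraction` (events among the moved; `NA` when
#'   none moved), `n_intermediate` (old-model intermediate total),
#'   `moved_fraction` (`n_moved / n_intermediate`), and
#'   `n_moved_to_low` (intermediate -> low, both outcomes).
#' @export
intermediate_to_high_summary <- function(table) {
  stopifnot(inherits(table, "reclassification_table"))
  moved_e <- table$events["intermediate", "high"]
  moved_ne <- table$non_events["intermediate", "high"]
  n_moved <- moved_e + moved_ne
  n_int <- sum(table$events["intermediate", ]) + sum(table$non_events["intermediate", ])
  list(
    n_moved = n_moved,
    n_events_moved = moved_e,
    event_fraction = if (n_moved > 0) moved_e / n_moved else NA_real_,
    n_intermediate = n_int,
    moved_fraction = if (n_int > 0) n_moved / n_int else NA_real_,
    n_moved_to_low = table$events["intermediate", "low"] +
      table$non_events["intermediate", "low"]
  )
}

#' Write a reclassification table as CSV
#'
#' Two labelled 3x3 blocks (events, then non-events), rows = old-model
#' stratum, columns = new-model stratum.
#'
#' @param table A `reclassification_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reclassification_csv <- function(table, path) {
  stopifnot(inherits(table, "reclassification_table"))
  block <- function(m, label) {
    rbind(
      c("block", "old_group", risk_levels()),
      cbind(label, risk_levels(), matrix(as.character(m), 3, 3))
    )
  }
  out <- rbind(block(table$events, "events"), block(table$non_events, "non_events"))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a reclassification table written by [write_reclassification_csv()]
#'
#' @param path CSV path.
#' @return A `reclassification_table`.
#' @export
read_reclassification_csv <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character")
  pick <- function(label) {
    rows <- raw[raw[[1]] == label, , drop = FALSE]
    m <- matrix(as.integer(as.matrix(rows[, 3:5])), 3, 3,
                dimnames = list(old = risk_levels(), new = risk_levels()))
    m
  }
  ev <- pick("events")
  ne <- pick("non_events")
  structure(
    list(events = ev, non_events = ne,
         n_events = sum(ev), n_non_events = sum(ne)),
    class = "reclassification_table"
  )
}

#' Serialise a reclassification summary to JSON
#'
#' Carries both raw fractions and display-rounded percentage strings
#' (one decimal, halves away from zero) so consumers can compare on raw
#' values and print the conventional rounded form.
#'
#' @param summary A `reclass_summary`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string, invisibly if written to a file.
#' @export
reclass_summary_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "reclass_summary"))
  obj <- unclass(summary)
  obj$display <- list(
    event_improvement = fmt_percent(summary$event_improvement),
    non_event_improvement = fmt_percent(summary$non_event_improvement),
    overall_improvement = fmt_percent(summary$overall_improvement),
    nri = fmt_percent(summary$nri)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
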