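#' Cohort CSV schema
#'
#' Column names and semantic types of the patient-level cohort CSV format.
#' Binary columns are encoded 0/1 (the reader also accepts true/false,
#' case-insensitively); empty cells denote missing values. Indicator
#' direction follows the prediction equations: `runny_nose_absent = 1` means
#' the patient has NO runny nose, `feels_ill = 1` means the patient reports
#' feeling ill.
#'
#' @return Named character vector mapping column name to semantic type.
#' @export
cohort_schema <- function() {
  c(
    patient_id               = "id",
    age_years                = "count",
    runny_nose_absent        = "binary",
    feels_ill                = "binary",
    current_smoker           = "binary",
    confusion_new_onset      = "binary",
    respiratory_rate_per_min = "positive",
    systolic_bp_mmHg         = "positive",
    diastolic_bp_mmHg        = "positive",
    oxygen_saturation_pct    = "saturation",
    crp_mg_per_l             = "nonneg",
    pct                      = "nonneg",
    mr_proadm_nmol_per_l     = "nonneg",
    consolidation            = "binary",
    antibiotics_after_xray   = "binary",
    hospital_referral        = "binary"
  )
}

binary_fields <- function() {
  names(cohort_schema())[cohort_schema() == "binary"]
}

#' Construct a patient cohort
#'
#' Wraps a data frame of patient records (one row per patient, columns as in
#' [cohort_schema()]) together with a provenance label. Missing optional
#' columns are added as all-missing; the result is validated.
#'
#' @param data Data frame with at least a `consolidation` column (binary
#'   outcome: consolidation on chest X ray).
#' @param provenance Free-text origin label, e.g. `"fixture"`, `"synthetic"`
#'   or `"user"`.
#' @param strict Logical; if `TRUE` (default) invariant violations are
#'   errors, otherwise warnings.
#' @return An object of class `pneumonia_cohort`.
#' @export
cohort <- function(data, provenance = "user", strict = TRUE) {
  if (!is.data.frame(data)) {
    stop_pneumorisk("`data` must be a data frame", class = "pneumorisk_input_error")
  }
  schema <- cohort_schema()
  if (nrow(data) < 1) {
    stop_pneumorisk("cohort must contain at least one record",
                    class = "pneumorisk_validation_error")
  }
  if (!"consolidation" %in% names(data)) {
    stop_pneumorisk("cohort data lack the required outcome column 'consolidation'",
                    class = "pneumorisk_schema_error")
  }
  extra <- setdiff(names(data), names(schema))
  if (length(extra) > 0) {
    warning("ignoring columns outside the cohort schema: ",
            paste(extra, collapse = ", "))
    data <- data[, setdiff(names(data), extra), drop = FALSE]
  }
  if (!"patient_id" %in% names(data)) {
    data$patient_id <- as.character(seq_len(nrow(data)))
  }
  for (col in setdiff(names(schema), names(data))) {
    data[[col]] <- if (col == "patient_id") as.character(NA) else NA_real_
  }
  data <- data[, names(schema)]
  row.names(data) <- NULL
  data$patient_id <- as.character(data$patient_id)
  for (col in setdiff(names(schema), "patient_id")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  obj <- structure(
    list(data = data, provenance = as.character(provenance)[1]),
    class = "pneumonia_cohort"
  )
  validate_cohort(obj, strict = strict)
  obj
}

#' Validate a cohort against the data-model invariants
#'
#' Checks: at least one record; unique patient ids; binary fields restricted
#' to \{0, 1, missing\}; non-missing outcome; non-negative ages and
#' biomarkers; oxygen saturation within \[50, 100\]; diastolic below systolic
#' pressure where both are present.
#'
#' @param x A `pneumonia_cohort`.
#' @param strict Logical; violations are errors when `TRUE`, warnings
#'   otherwise.
#' @return `x`, invisibly.
#' @export
validate_cohort <- function(x, strict = TRUE) {
  stopifnot(inherits(x, "pneumonia_cohort"))
  d <- x$data
  complain <- function(msg) {
    if (strict) stop_pneumorisk(msg, class = "pneumorisk_validation_error")
    warning(msg, call. = FALSE)
  }
  if (nrow(d) < 1) complain("cohort must contain at least one record")
  if (anyDuplicated(d$patient_id)) {
    complain(paste0("duplicate patient_id values: ",
                    paste(unique(d$patient_id[duplicated(d$patient_id)]), collapse = ", ")))
  }
  for (col in binary_fields()) {
    if (!is_binary01(d[[col]])) {
      complain(paste0("column '", col, "' contains values outside {0, 1, missing}"))
    }
  }
  if (anyNA(d$consolidation)) {
    complain(paste0(sum(is.na(d$consolidation)),
                    " record(s) have a missing outcome (consolidation)"))
  }
  if (any(d$age_years < 0, na.rm = TRUE)) complain("negative age_years")
  for (col in c("crp_mg_per_l", "pct", "mr_proadm_nmol_per_l")) {
    if (any(d[[col]] < 0, na.rm = TRUE)) complain(paste0("negative ", col))
  }
  sat <- d$oxygen_saturation_pct
  if (any(sat < 50 | sat > 100, na.rm = TRUE)) {
    complain("oxygen_saturation_pct outside [50, 100]")
  }
  both <- !is.na(d$systolic_bp_mmHg) & !is.na(d$diastolic_bp_mmHg)
  if (any(d$diastolic_bp_mmHg[both] >= d$systolic_bp_mmHg[both])) {
    complain("diastolic blood pressure must be below systolic where both are recorded")
  }
  invisible(x)
}

#' @export
print.pneumonia_cohort <- function(x, ...) {
  d <- x$data
  cat("<pneumonia_cohort> ", nrow(d), " patients (provenance: ", x$provenance, ")\n",
      sep = "")
  cat("  events (consolidation = 1): ", sum(d$consolidation == 1, na.rm = TRUE),
      "; non-events: ", sum(d$consolidation == 0, na.rm = TRUE), "\n", sep = "")
  n_miss <- vapply(d, function(col) sum(is.na(col)), integer(1))
  n_miss <- n_miss[n_miss > 0]
  if (length(n_miss) > 0) {
    cat("  missing values: ",
        paste(names(n_miss), n_miss, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname cohort
#' @param x A `pneumonia_cohort`.
#' @export
cohort_data <- function(x) {
  stopifnot(inherits(x, "pneumonia_cohort"))
  x$data
}

#' @rdname cohort
#' @export
n_records <- function(x) nrow(cohort_data(x))

#' @rdname cohort
#' @export
n_events <- function(x) sum(cohort_data(x)$consolidation == 1, na.rm = TRUE)

parse_numeric_column <- function(raw, col) {
  raw <- trimws(raw)
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & is.na(out))
  if (length(bad) > 0) {
    stop_pneumorisk("malformed numeric value '", raw[bad[1]], "' in column '",
                    col, "', row ", bad[1], class = "pneumorisk_parse_error")
  }
  out[raw == ""] <- NA_real_
  out
}

parse_binary_column <- function(raw, col) {
  raw <- trimws(raw)
  low <- tolower(raw)
  out <- rep(NA_real_, length(raw))
  out[low %in% c("1", "true")] <- 1
  out[low %in% c("0", "false")] <- 0
  bad <- which(!is.na(raw) & raw != "" & is.na(out))
  if (length(bad) > 0) {
    stop_pneumorisk("malformed binary value '", raw[bad[1]], "' in column '",
                    col, "', row ", bad[1],
                    " (expected 0/1 or true/false)", class = "pneumorisk_parse_error")
  }
  out
}

#' Read a cohort from CSV
#'
#' Reads a patient-level CSV in the [cohort_schema()] format. Empty cells
#' become missing values; binary columns accept 0/1 and true/false. Columns
#' outside the schema are ignored with a warning; schema columns absent from
#' the file are filled with missing values. A missing `consolidation` column
#' is a schema error. If `patient_id` is absent, row numbers are used.
#'
#' @param path Path to a CSV file.
#' @param strict Logical; passed to [validate_cohort()]. Default `TRUE`
#'   (fail fast on invariant violations).
#' @param provenance Provenance label for the resulting cohort.
#' @return A `pneumonia_cohort`.
#' @export
read_cohort <- function(path, strict = TRUE, provenance = "user") {
  if (!file.exists(path)) {
    stop_pneumorisk("file not found: ", path, class = "pneumorisk_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0))
  schema <- cohort_schema()
  if (!"consolidation" %in% names(raw)) {
    stop_pneumorisk("input CSV lacks the required outcome column 'consolidation'",
                    class = "pneumorisk_schema_error")
  }
  parsed <- data.frame(row.names = seq_len(nrow(raw)))
  if ("patient_id" %in% names(raw)) {
    parsed$patient_id <- trimws(raw$patient_id)
  }
  for (col in intersect(names(schema), names(raw))) {
    if (col == "patient_id") next
    parsed[[col]] <- if (schema[[col]] == "binary") {
      parse_binary_column(raw[[col]], col)
    } else {
      parse_numeric_column(raw[[col]], col)
    }
  }
  extra <- setdiff(names(raw), names(schema))
  if (length(extra) > 0) {
    warning("ignoring columns outside the cohort schema: ",
            paste(extra, collapse = ", "))
  }
  cohort(parsed, provenance = provenance, strict = strict)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values are written as empty cells and
#' numeric values with enough significant digits that a write/read round trip
#' reproduces the cohort exactly.
#'
#' @param x A `pneumonia_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "pneumonia_cohort"))
  d <- cohort_data(x)
  out <- d
  for (col in setdiff(names(d), "patient_id")) {
    v <- d[[col]]
    s <- ifelse(is.na(v), "",
                ifelse(v == round(v) & abs(v) < 1e15,
                       sprintf("%.0f", v), sprintf("%.17g", v)))
    out[[col]] <- s
  }
  out$patient_id[is.na(d$patient_id)] <- ""
  ok <- tryCatch(
    {
      utils::write.table(out, path, sep = ",", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) {
    stop_pneumorisk("cannot write cohort to '", path, "': ",
                    conditionMessage(ok), class = "pneumorisk_io_error")
  }
  invisible(path)
}

#' Complete-case subset of a cohort
#'
#' Keeps the records with non-missing values for every field in
#' `required_fields`, preserving record order. The number of records dropped
#' because of each field is attached as the `"exclusions"` attribute (a named
#' integer vector; a record missing several required fields is counted under
#' each).
#'
#' @param x A `pneumonia_cohort`.
#' @param required_fields Character vector of schema field names (may be
#'   empty, in which case the cohort is returned unchanged).
#' @return A `pneumonia_cohort` of the complete cases, with attribute
#'   `"exclusions"`.
#' @export
complete_case_subset <- function(x, required_fields = character(0)) {
  stopifnot(inherits(x, "pneumonia_cohort"))
  d <- cohort_data(x)
  unknown <- setdiff(required_fields, names(cohort_schema()))
  if (length(unknown) > 0) {
    stop_pneumorisk("unknown field name(s): ", paste(unknown, collapse = ", "),
                    class = "pneumorisk_input_error")
  }
  if (length(required_fields) == 0) {
    keep <- rep(TRUE, nrow(d))
    dropped <- integer(0)
  } else {
    miss <- matrix(FALSE, nrow(d), length(required_fields))
    for (j in seq_along(required_fields)) {
      miss[, j] <- is.na(d[[required_fields[j]]])
    }
    keep <- rowSums(miss) == 0
    dropped <- stats::setNames(colSums(miss), required_fields)
  }
  kept <- d[keep, , drop = FALSE]
  row.names(kept) <- NULL
  out <- structure(
    list(data = kept, provenance = x$provenance),
    class = "pneumonia_cohort"
  )
  attr(out, "exclusions") <- dropped
  out
}
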