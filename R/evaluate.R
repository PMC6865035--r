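#' ROC curve and AUC for a continuous score
#'
#' Computes the receiver operating characteristic curve by sweeping the
#' unique score values as thresholds, and the area under it, which equals
#' the Mann-Whitney concordance probability with ties credited one half.
#'
#' @param scores Numeric scores (higher = more likely an event); no missing
#'   values (handle missingness upstream, e.g. [complete_case_subset()]).
#' @param outcomes Binary outcome vector (1 = event).
#' @return An object of class `roc_result`: `auc`, `n_events`,
#'   `n_non_events`, and `roc_points` (data frame with `threshold`, `fpr`,
#'   `tpr`, ordered from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, outcomes) {
  if (anyNA(scores) || anyNA(outcomes)) {
    stop_pneumorisk("scores and outcomes must be non-missing",
                    class = "pneumorisk_input_error")
  }
  if (length(scores) != length(outcomes) || !is_binary01(outcomes)) {
    stop_pneumorisk("`outcomes` must be 0/1 of the same length as `scores`",
                    class = "pneumorisk_input_error")
  }
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) {
    stop_pneumorisk("need at least one event and one non-event",
                    class = "pneumorisk_input_error")
  }
  r <- pROC::roc(response = outcomes, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- data.frame(threshold = r$thresholds,
                    fpr = 1 - r$specificities,
                    tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  structure(
    list(auc = as.numeric(pROC::auc(r)), n_events = n1, n_non_events = n0,
         roc_points = pts),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", sprintf("%.4f", x$auc),
      " (", x$n_events, " events / ", x$n_non_events, " non-events, ",
      nrow(x$roc_points), " curve points)\n", sep = "")
  invisible(x)
}

#' Write ROC curve points as CSV
#'
#' @param roc A `roc_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.csv(roc$roc_points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping: records are sorted by predicted probability and
#' split into `n_groups` equal-sized groups, with tied probabilities kept in
#' the same group (so fewer groups can result). The statistic sums
#' `(observed - expected)^2 / expected` over groups and both outcome classes;
#' groups whose expected event or non-event count is zero are merged with a
#' neighbour (with a warning). Degrees of freedom default to the number of
#' groups actually used minus 2.
#'
#' @param probs Predicted probabilities, strictly inside (0, 1).
#' @param outcomes Binary outcome vector (1 = event).
#' @param n_groups Number of risk groups (default 10).
#' @return An object of class `calibration_result`: `hl_statistic`, `hl_df`,
#'   `hl_p`, `n_groups` (groups actually used), and the per-group summary
#'   `groups` (observed/expected by class).
#' @export
hosmer_lemeshow <- function(probs, outcomes, n_groups = 10) {
  if (anyNA(probs) || anyNA(outcomes) || any(probs <= 0 | probs >= 1)) {
    stop_pneumorisk("probabilities must be non-missing and strictly inside (0, 1)",
                    class = "pneumorisk_input_error")
  }
  if (!is_binary01(outcomes) || length(probs) != length(outcomes)) {
    stop_pneumorisk("`outcomes` must be 0/1 of the same length as `probs`",
                    class = "pneumorisk_input_error")
  }
  n <- length(probs)
  if (n < n_groups) {
    stop_pneumorisk("need at least as many records as groups",
                    class = "pneumorisk_input_error")
  }
  ord <- order(probs)
  g <- ceiling(seq_len(n) * n_groups / n)
  # keep tied probabilities in one group: each distinct value takes the
  # group of its first (sorted) occurrence
  sorted_p <- probs[ord]
  g <- g[match(sorted_p, sorted_p)]
  group_of <- integer(n)
  group_of[ord] <- g
  agg <- function(gid) {
    ids <- sort(unique(gid))
    t(vapply(ids, function(k) {
      sel <- gid == k
      c(n = sum(sel), obs1 = sum(outcomes[sel]), exp1 = sum(probs[sel]))
    }, numeric(3)))
  }
  tab <- agg(group_of)
  # merge groups with a zero expected count into the neighbour above
  merged <- FALSE
  repeat {
    exp0 <- tab[, "n"] - tab[, "exp1"]
    bad <- which(tab[, "exp1"] == 0 | exp0 == 0)
    if (length(bad) == 0 || nrow(tab) <= 2) break
    i <- bad[1]
    j <- if (i < nrow(tab)) i + 1 else i - 1
    tab[j, ] <- tab[j, ] + tab[i, ]
    tab <- tab[-i, , drop = FALSE]
    merged <- TRUE
  }
  if (merged) {
    warning("groups with zero expected counts were merged; ",
            nrow(tab), " groups used")
  }
  obs1 <- tab[, "obs1"]; exp1 <- tab[, "exp1"]
  obs0 <- tab[, "n"] - obs1; exp0 <- tab[, "n"] - exp1
  stat <- sum((obs1 - exp1)^2 / exp1 + (obs0 - exp0)^2 / exp0)
  df <- nrow(tab) - 2
  # with fewer than 3 groups the reference distribution is degenerate
  p_val <- if (df >= 1) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  structure(
    list(hl_statistic = stat, hl_df = df,
         hl_p = p_val,
         n_groups = nrow(tab),
         groups = data.frame(n = tab[, "n"], observed_events = obs1,
                             expected_events = exp1)),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> Hosmer-Lemeshow chi-square = ",
      sprintf("%.3f", x$hl_statistic), " (df = ", x$hl_df, ", P = ",
      sprintf("%.3f", x$hl_p), "; ", x$n_groups, " groups)\n", sep = "")
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' Rescaled likelihood-ratio R-squared for binary outcome models:
#' `(1 - exp(2 (ll0 - ll1) / n)) / (1 - exp(2 ll0 / n))`, bounded in
#' \[0, 1\] with 0 at the null model and 1 at a saturated fit.
#'
#' @param loglik_model Log-likelihood of the fitted model.
#' @param loglik_null Log-likelihood of the intercept-only model.
#' @param n Number of observations.
#' @return A number in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  if (n <= 0) stop_pneumorisk("n must be positive", class = "pneumorisk_input_error")
  if (loglik_model < loglik_null - 1e-8) {
    stop_pneumorisk("model log-likelihood cannot be below the null log-likelihood",
                    class = "pneumorisk_input_error")
  }
  cox_snell <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  max_r2 <- 1 - exp(2 * loglik_null / n)
  cox_snell / max_r2
}

#' Compare biomarkers by discriminative ability
#'
#' Computes each biomarker's ROC AUC for the outcome on its own complete-case
#' subset and ranks markers by descending AUC. All-missing or single-class
#' subsets are skipped with a warning.
#'
#' @param x A `pneumonia_cohort`.
#' @param biomarkers Character vector of biomarker column names (defaults to
#'   CRP, PCT, MR-proADM).
#' @param outcome Outcome column (default `"consolidation"`).
#' @return Data frame with columns `biomarker`, `auc`, `n`, `n_events`,
#'   sorted by descending AUC; the full `roc_result`s are attached as the
#'   `"roc"` attribute (named list).
#' @export
compare_biomarkers <- function(x,
                               biomarkers = c("crp_mg_per_l", "pct",
                                              "mr_proadm_nmol_per_l"),
                               outcome = "consolidation") {
  stopifnot(inherits(x, "pneumonia_cohort"))
  if (length(biomarkers) < 1) {
    stop_pneumorisk("no biomarkers given", class = "pneumorisk_input_error")
  }
  d <- cohort_data(x)
  rocs <- list()
  rows <- list()
  for (bm in biomarkers) {
    if (!bm %in% names(d)) {
      stop_pneumorisk("unknown biomarker column '", bm, "'",
                      class = "pneumorisk_input_error")
    }
    keep <- !is.na(d[[bm]]) & !is.na(d[[outcome]])
    if (!any(keep) || length(unique(d[[outcome]][keep])) < 2) {
      warning("biomarker '", bm, "' skipped: all missing or single-class subset")
      next
    }
    r <- roc_auc(d[[bm]][keep], d[[outcome]][keep])
    rocs[[bm]] <- r
    rows[[bm]] <- data.frame(biomarker = bm, auc = r$auc,
                             n = r$n_events + r$n_non_events,
                             n_events = r$n_events)
  }
  if (length(rows) == 0) {
    stop_pneumorisk("no biomarker could be evaluated",
                    class = "pneumorisk_input_error")
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "roc") <- rocs
  out
}
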