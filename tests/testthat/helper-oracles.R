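# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# all-pairs Mann-Whitney concordance with half credit for ties
brute_force_auc <- function(scores, outcomes) {
  ev <- scores[outcomes == 1]
  ne <- scores[outcomes == 0]
  total <- 0
  for (e in ev) {
    total <- total + sum(e > ne) + 0.5 * sum(e == ne)
  }
  total / (length(ev) * length(ne))
}

# expand a 2x2 table (a = exposed events, b = unexposed events,
# c = exposed non-events, d = unexposed non-events) to patient-level rows
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    y = c(rep(1, a + b), rep(0, c + d)),
    x = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  )
}

# a tiny well-formed cohort data frame for I/O tests
small_cohort_df <- function(n = 3) {
  data.frame(
    patient_id = paste0("A", seq_len(n)),
    age_years = seq(40, by = 5, length.out = n),
    runny_nose_absent = rep_len(c(0, 1), n),
    feels_ill = rep_len(c(1, 0), n),
    crp_mg_per_l = seq(5, by = 12.345, length.out = n),
    consolidation = rep_len(c(0, 1), n)
  )
}

write_cohort_csv_text <- function(lines, path) {
  writeLines(lines, path)
  path
}
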