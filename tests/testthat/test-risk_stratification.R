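test_that("risk groups follow the 2.5%/20% bands with closed intermediate boundaries", {
  expect_equal(as.character(assign_risk_group(c(0.01107, 0.31, 0.025, 0.20))),
               c("low", "high", "intermediate", "intermediate"))
  expect_true(is.ordered(assign_risk_group(0.5)))
  expect_error(assign_risk_group(1.2), class = "pneumorisk_input_error")
  expect_error(assign_risk_group(c(0.1, NA)), class = "pneumorisk_input_error")
  expect_error(risk_thresholds(0.3, 0.2), class = "pneumorisk_input_error")
})

test_that("stratify_cohort summarises groups, events and exclusions", {
  one <- cohort(data.frame(runny_nose_absent = 0, feels_ill = 0,
                           consolidation = 0))
  s <- stratify_cohort(one, published_clinical_model())
  expect_equal(s$group_counts, c(low = 1L, intermediate = 0L, high = 0L))

  fx <- fixture_cohort()
  s <- stratify_cohort(fx, published_crp_model())
  expect_equal(s$n_used, 242)
  expect_equal(unname(s$n_excluded["crp_mg_per_l"]), 6)
  expect_equal(s$group_counts, c(low = 49L, intermediate = 125L, high = 68L))
  expect_equal(s$events_per_group, c(low = 0L, intermediate = 8L, high = 22L))

  empty <- cohort(data.frame(runny_nose_absent = NA_real_, feels_ill = 1,
                             consolidation = 1), strict = FALSE)
  expect_error(stratify_cohort(empty, published_clinical_model()),
               "no complete cases")
})

test_that("reclassification tables cross-tabulate by outcome and ignore patient order", {
  old <- c("low", "intermediate", "high", "intermediate")
  new <- c("low", "high", "high", "low")
  y <- c(0, 1, 1, 0)
  tab <- build_reclassification_table(old, new, y)
  expect_equal(sum(tab$events), 2)
  expect_equal(sum(tab$non_events), 2)
  expect_equal(tab$events["intermediate", "high"], 2 - 1)  # one event moved up
  expect_equal(tab$non_events["intermediate", "low"], 1)

  perm <- sample(seq_along(old))
  tab2 <- build_reclassification_table(old[perm], new[perm], y[perm])
  expect_identical(tab2$events, tab$events)
  expect_identical(tab2$non_events, tab$non_events)

  same <- build_reclassification_table(old, old, y)
  expect_true(all(same$events[upper.tri(same$events)] == 0))
  expect_true(all(same$events[lower.tri(same$events)] == 0))
  expect_true(all(same$non_events[upper.tri(same$non_events)] == 0))

  expect_error(build_reclassification_table(old[-1], new, y),
               class = "pneumorisk_input_error")
})

test_that("row sums of the reclassification table match each model's marginals", {
  res <- reclassify_cohort(fixture_cohort(), published_clinical_model(),
                           published_crp_model())
  tot <- res$table$events + res$table$non_events
  expect_equal(unname(rowSums(tot)), unname(res$old$group_counts))
  expect_equal(unname(colSums(tot)), unname(res$new$group_counts))
  expect_equal(unname(rowSums(res$table$events)),
               unname(res$old$events_per_group))
})

test_that("improvement statistics follow their defining arithmetic", {
  tab <- build_reclassification_table(
    old = c(rep("intermediate", 6), rep("high", 2), rep("low", 4)),
    new = c(rep("high", 4), rep("intermediate", 2), rep("intermediate", 2),
            rep("low", 4)),
    outcomes = c(1, 1, 1, 0, 1, 0, 1, 0, 0, 0, 0, 0)
  )
  s <- reclassification_summary(tab)
  # events: 3 up, 1 down of 5; non-events: 1 up, 1 down of 7
  expect_equal(s$event_improvement, (3 - 1) / 5)
  expect_equal(s$non_event_improvement, (1 - 1) / 7)
  expect_equal(s$overall_improvement, (3 - 1 + 1 - 1) / 12)
  expect_equal(s$nri, s$event_improvement + s$non_event_improvement)

  # diagonal-only table: all improvements zero
  diag_tab <- build_reclassification_table(
    c("low", "high"), c("low", "high"), c(0, 1))
  sd <- reclassification_summary(diag_tab)
  expect_equal(sd$overall_improvement, 0)
  expect_equal(sd$nri, 0)
  ih <- intermediate_to_high_summary(diag_tab)
  expect_equal(ih$n_moved, 0)
  expect_true(is.na(ih$event_fraction))

  # zero denominators are refused by name
  no_events <- build_reclassification_table("low", "low", 0)
  expect_error(reclassification_summary(no_events), "no events")
})

test_that("swapping old and new models flips the sign of every improvement", {
  fx <- fixture_cohort()
  fwd <- reclassification_summary(
    reclassify_cohort(fx, published_clinical_model(), published_crp_model())$table)
  rev <- reclassification_summary(
    reclassify_cohort(fx, published_crp_model(), published_clinical_model())$table)
  expect_equal(rev$overall_improvement, -fwd$overall_improvement)
  expect_equal(rev$event_improvement, -fwd$event_improvement)
  expect_equal(rev$non_event_improvement, -fwd$non_event_improvement)
  expect_equal(rev$nri, -fwd$nri)
})

test_that("adding the CRP term never moves a covariate pattern down a stratum", {
  # exhaustive over the 8 covariate patterns: the structural reason the
  # published lower triangles are zero
  grid <- expand.grid(runny_nose_absent = 0:1, feels_ill = 0:1, crp_gt_30 = 0:1)
  old <- assign_risk_group(predict_probability(published_clinical_model(), grid))
  new <- assign_risk_group(predict_probability(published_crp_model(), grid))
  expect_true(all(as.integer(new) >= as.integer(old)))
})

test_that("decisive fraction counts the low and high strata", {
  expect_equal(decisive_fraction(c(low = 2L, intermediate = 0L, high = 3L)), 1)
  expect_equal(decisive_fraction(c(low = 0L, intermediate = 9L, high = 0L)), 0)
  expect_error(decisive_fraction(c(low = 0L, intermediate = 0L, high = 0L)),
               class = "pneumorisk_input_error")
  expect_error(decisive_fraction(c(a = 1)), class = "pneumorisk_input_error")
})

test_that("reclassification table and summary serialise and read back", {
  res <- reclassify_cohort(fixture_cohort(), published_clinical_model(),
                           published_crp_model())
  path <- withr::local_tempfile(fileext = ".csv")
  write_reclassification_csv(res$table, path)
  back <- read_reclassification_csv(path)
  expect_identical(back$events, res$table$events)
  expect_identical(back$non_events, res$table$non_events)

  s <- reclassification_summary(res$table)
  parsed <- jsonlite::fromJSON(reclass_summary_json(s))
  expect_equal(parsed$overall_improvement, s$overall_improvement)
  expect_equal(parsed$display$overall_improvement, "-3.7%")
  expect_equal(parsed$display$nri, "18.6%")
})
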