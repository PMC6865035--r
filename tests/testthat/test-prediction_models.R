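test_that("published equations carry the printed constants", {
  clin <- published_clinical_model()
  expect_equal(clin$intercept, -4.492)
  expect_equal(clin$coefficients,
               c(runny_nose_absent = 1.142, feels_ill = 2.550))

  crp <- published_crp_model()
  expect_equal(crp$intercept, -4.797)
  expect_equal(crp$coefficients,
               c(runny_nose_absent = 1.230, feels_ill = 2.378,
                 crp_gt_30 = 1.572))

  expect_equal(get_published_model("clinical")$label, "clinical")
  expect_error(get_published_model("nope"), class = "pneumorisk_input_error")

  # JSON round trip keeps the constants exactly
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(crp, path)
  back <- model_from_json(path)
  expect_equal(back$coefficients, crp$coefficients)
  expect_equal(back$intercept, crp$intercept)
})

test_that("predict_probability evaluates the logistic link as printed", {
  clin <- published_clinical_model()
  crp <- published_crp_model()
  # expected values computed directly as plogis(linear predictor)
  expect_equal(
    predict_probability(clin, data.frame(runny_nose_absent = 0, feels_ill = 0)),
    plogis(-4.492), tolerance = 1e-12)
  expect_equal(round(predict_probability(
    clin, data.frame(runny_nose_absent = 0, feels_ill = 0)), 5), 0.01107)
  expect_equal(
    predict_probability(clin, data.frame(runny_nose_absent = 1, feels_ill = 1)),
    plogis(-4.492 + 1.142 + 2.550), tolerance = 1e-12)
  expect_equal(
    predict_probability(crp, data.frame(runny_nose_absent = 1, feels_ill = 1,
                                        crp_gt_30 = 1)),
    plogis(-4.797 + 1.230 + 2.378 + 1.572), tolerance = 1e-12)

  # crp_gt_30 is derived from continuous CRP when not supplied
  expect_equal(
    predict_probability(crp, data.frame(runny_nose_absent = 1, feels_ill = 1,
                                        crp_mg_per_l = c(45, 30))),
    plogis(-4.797 + 1.230 + 2.378 + c(1.572, 0)))

  expect_error(
    predict_probability(clin, data.frame(runny_nose_absent = NA, feels_ill = 1)),
    class = "pneumorisk_missing_predictor_error")
  expect_error(
    predict_probability(crp, data.frame(runny_nose_absent = 1, feels_ill = 1)),
    class = "pneumorisk_missing_predictor_error")
})

test_that("predicted probability is strictly increasing in positive-coefficient covariates", {
  crp <- published_crp_model()
  grid <- expand.grid(runny_nose_absent = 0:1, feels_ill = 0:1, crp_gt_30 = 0:1)
  p <- predict_probability(crp, grid)
  expect_true(all(p > 0 & p < 1))
  for (term in names(crp$coefficients)) {
    up <- grid; up[[term]] <- 1
    down <- grid; down[[term]] <- 0
    expect_true(all(predict_probability(crp, up) >
                      predict_probability(crp, down)))
  }
})

test_that("fit on a single binary predictor equals the 2x2 cross-product odds ratio", {
  set.seed(11)
  for (rep in 1:20) {
    tab <- sample(3:40, 4)  # a, b, c, d without zero cells
    d <- expand_2x2(tab[1], tab[2], tab[3], tab[4])
    fit <- fit_logistic(d, outcome = "y", predictors = "x")
    oracle_or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
    expect_equal(unname(fit$odds_ratios), oracle_or, tolerance = 1e-6)
    expect_equal(unname(exp(fit$model$coefficients)), oracle_or,
                 tolerance = 1e-6)
    expect_equal(fit$n_used, sum(tab))
    expect_true(fit$or_ci95["x", "lower"] < oracle_or)
    expect_true(fit$or_ci95["x", "upper"] > oracle_or)
  }
})

test_that("univariate odds ratio matches the printed antibiotic-treatment contrast", {
  # 19/33 treated among treatable disease vs 64/199 among the rest:
  # OR = (19 * 135) / (14 * 64)
  d <- expand_2x2(19, 64, 33 - 19, 199 - 64)
  names(d) <- c("treatable", "antibiotics")
  fit <- univariate_or(d, outcome = "antibiotics", predictor = "treatable")
  expect_equal(unname(fit$odds_ratios), (19 * 135) / (14 * 64),
               tolerance = 1e-6)
  expect_equal(round(unname(fit$odds_ratios), 3), 2.863)
})

test_that("separation is flagged, not returned as silent garbage", {
  d <- data.frame(y = rep(c(0, 1), each = 20))
  d$x <- d$y
  expect_error(univariate_or(d, outcome = "y", predictor = "x"),
               class = "pneumorisk_separation_error")
  fit <- fit_logistic(d, outcome = "y", predictors = "x",
                      error_on_separation = FALSE)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation")
})

test_that("fit_logistic validates degenerate inputs", {
  d <- small_cohort_df(10)
  all0 <- d; all0$consolidation <- 0
  expect_error(fit_logistic(all0, predictors = "feels_ill"),
               "at least one event")
  const <- d; const$feels_ill <- 1
  expect_error(fit_logistic(const, predictors = "feels_ill"), "constant")
  expect_error(fit_logistic(d, predictors = "no_such_column"),
               class = "pneumorisk_input_error")
})

test_that("a null predictor is estimated near zero with nominal CI coverage", {
  covered <- 0
  for (s in 1:20) {
    spec <- synthetic_cohort_spec(
      n = 50000, seed = s,
      model = logistic_model(stats::qlogis(0.12), c(feels_ill = 0),
                             label = "null")
    )
    d <- cohort_data(simulate_cohort(spec))
    # runny nose plays no role in the generative model
    fit <- fit_logistic(d, predictors = "runny_nose_absent")
    expect_lt(abs(unname(fit$model$coefficients)), 0.1)
    ci <- fit$or_ci95["runny_nose_absent", ]
    if (ci["lower"] < 1 && ci["upper"] > 1) covered <- covered + 1
  }
  expect_gte(covered, 18)
})

test_that("CRB-65 scores follow the four-criterion definition and are monotone", {
  expect_equal(crb65_score(0, 25, 120, 80, 70), 1L)  # age only
  expect_equal(crb65_score(1, 30, 85, 55, 50), 3L)   # C + R + B; RR >= 30 inclusive
  expect_equal(crb65_score(0, 16, 130, 85, 40), 0L)
  # blood pressure counts once even when both criteria are met
  expect_equal(crb65_score(0, 16, 85, 55, 40), 1L)
  expect_equal(crb65_score(1, 31, 85, 55, 70), 4L)
  expect_error(crb65_score(NA, 16, 130, 85, 40),
               class = "pneumorisk_input_error")

  # monotone non-decreasing in each criterion over a grid
  grid <- expand.grid(conf = 0:1, rr = c(16, 30), sbp = c(85, 120),
                      dbp = c(55, 80), age = c(50, 65))
  grid$dbp <- pmin(grid$dbp, grid$sbp - 5)
  sc <- with(grid, crb65_score(conf, rr, sbp, dbp, age))
  expect_true(all(sc >= 0 & sc <= 4))
  worse <- with(grid, crb65_score(pmax(conf, 1), pmax(rr, 30),
                                  pmin(sbp, 85), pmin(dbp, 55),
                                  pmax(age, 65)))
  expect_true(all(worse >= sc))
})

test_that("CRP guideline bands split at 20 and 100 mg/l", {
  expect_equal(as.character(crp_band(c(15, 150, 20, 100, 20.5))),
               c("rule_out", "treat", "intermediate", "intermediate",
                 "intermediate"))
  expect_true(is.na(crp_band(NA_real_)))
  expect_error(crp_band(-1), class = "pneumorisk_input_error")
})

test_that("biomarker dichotomisation is strict and propagates missingness", {
  expect_equal(biomarker_indicator(45, 30), 1)
  expect_equal(biomarker_indicator(0.646, 0.646), 0)  # tie scores 0
  expect_equal(biomarker_indicator(1.2, 1.00), 1)
  expect_true(is.na(biomarker_indicator(NA_real_, 30)))
  expect_error(biomarker_indicator(-2, 30), class = "pneumorisk_input_error")
  expect_error(biomarker_indicator(5, 0), class = "pneumorisk_input_error")
})
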