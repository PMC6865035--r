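---
title: "Predicting pneumonia in primary care: models, risk strata and reclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pneumonia in primary care: models, risk strata and reclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumorisk)
```

## The clinical setting and the model

Patients who present to their general practitioner with an acute respiratory
tract infection (complaints for less than three weeks) occasionally have
community-acquired pneumonia, operationalised here as a consolidation on
chest X ray. Two logistic equations predict that outcome from bedside
information:

* **Clinical model** — `logit(p) = -4.492 + 1.142 * runny_nose_absent +
  2.550 * feels_ill`. Both predictors are 0/1 indicators; note the direction
  of the first: 1 codes the *absence* of a runny nose, which raises pneumonia
  risk (a runny nose points to an upper-airway viral infection).
* **CRP-augmented model** — `logit(p) = -4.797 + 1.230 * runny_nose_absent +
  2.378 * feels_ill + 1.572 * crp_gt_30`, where `crp_gt_30` indicates
  C-reactive protein strictly above 30 mg/l.

`published_clinical_model()` and `published_crp_model()` hold these constants
verbatim; `predict_probability()` evaluates the logistic link. The package
takes the printed coefficients at face value — whether they were refitted
after covariate screening or extracted from a larger model is not stated in
the source, and cannot be re-derived without the raw cohort. The screening
workflow itself (univariate then multivariate logistic regression at
P < 0.10) is available through `fit_logistic()` / `univariate_or()`, but no
automatic variable-selection routine is provided: the printed equations are
the reproducible artifact.

## Risk strata and their conventions

`assign_risk_group()` maps probabilities to three predefined strata designed
to track treatment decisions:

| stratum      | band          | consequence                          |
|--------------|---------------|--------------------------------------|
| low          | p < 2.5%      | withhold antibiotics, no chest X ray |
| intermediate | 2.5% ≤ p ≤ 20%| diagnostic uncertainty remains       |
| high         | p > 20%       | treat; chest X ray adds little       |

The band wording ("less than 2.5%", "above 20%") makes the outer strata
strict inequalities, so the intermediate band is closed on both ends. This
convention is documented rather than consequential: with the published
coefficients no covariate pattern lands exactly on a boundary. The cut
points are `risk_thresholds()` defaults and can be changed, but 0.025/0.20
are the values the analysis is defined by.

Dichotomisations use strict ">" throughout (`biomarker_indicator()`): a CRP
of exactly 30 mg/l scores 0. The source notation ("CRP > 30 mg/l") implies
this but never discusses ties; we resolve them downward and say so
prominently, since a tie at the cutoff changes the predicted stratum for an
ill patient. PCT cutoffs are deliberately not defaulted — the external
algorithm they came from is not reproduced here — so any PCT dichotomisation
must be supplied explicitly.

## Reclassification arithmetic

`build_reclassification_table()` cross-tabulates old-model against new-model
strata separately for events and non-events. `reclassification_summary()`
computes:

* event improvement = (up − down) / n_events,
* non-event improvement = (down − up) / n_non_events,
* **ORI** = (up_events − down_events + down_non-events − up_non-events) /
  (n_events + n_non_events),
* **NRI** = event improvement + non-event improvement.

"Correct" counts *any* upward move for events and any downward move for
non-events, including single-step moves into or out of the intermediate
band. The source prose motivates reclassification by the decisive strata
only, but its own arithmetic (8 up-moves among 30 events, giving 26.7%, and
−9/242 overall) counts every move; we therefore count every move. ORI
weights each patient equally, which its authors prefer over NRI when events
are rare (30 events vs 212 non-events): the NRI for the same table is
+18.6%, with opposite sign to the ORI of −3.7%, purely because the event
group is 7 times smaller.

Percentages are displayed with one decimal, halves rounded away from zero
(`round_half_up()`), matching conventional clinical reporting; all raw
fractions are kept alongside so nothing accumulates rounding error.

## The fixture cohort: reconstructing patient-level data from printed counts

The published reclassification table fully determines the joint distribution
of (clinical stratum, CRP stratum, outcome) for the 242 analysed patients,
and the two equations map each of the 8 covariate patterns
(runny nose × feels ill × CRP indicator) to a unique stratum pair. That
pins down most, but not all, patient-level structure. `fixture_cohort()`
builds a deterministic 249-record cohort:

* 51 clinical-low non-events (runny nose present, not ill; 2 with CRP > 30),
* 16 intermediate events: 8 up-movers (ill, CRP > 30 — the only pattern that
  moves intermediate → high) and 8 stayers,
* 130 intermediate non-events: 15 up-movers and 115 stayers,
* 45 clinical-high patients (runny nose absent and ill): 14 events, 31
  non-events,
* 7 excluded records — 1 missing a clinical variable, 6 missing CRP. All
  seven must be non-events: the table's 30 events already exhaust the
  cohort's full event count.

Where the counts under-determine the data — which stay-pattern each stayer
occupies, the CRP status of clinical-high patients (who remain high either
way), the covariates of the excluded records —
`fixture_cohort()` makes one documented deterministic choice, and
`randomized_consistent_fixture(seed)` draws those free choices uniformly at
random under the same constraints. The test suite verifies over many seeds
that every randomisation yields the identical reclassification table,
improvement statistics and group prevalences: the headline results do not
depend on the unidentifiable degrees of freedom. Vitals are filled with
cohort medians (age 56, unremarkable vital signs, CRB-65 of 0), continuous
CRP with values consistent with its indicator (10 or 80 mg/l); PCT and
MR-proADM are left missing since no patient-level biomarker distributions
are published.

One denominator deserves a note: the "21% low risk" share of the clinical
model uses the 242 analysed patients (51/242 = 21.1%), not all 249; the
package computes it on the analysed set, via the joint complete cases that
`reclassify_cohort()` reports.

## The stochastic generator

`simulate_cohort(synthetic_cohort_spec(...))` draws covariates as
independent Bernoulli variables (defaults `p_runny_absent = 0.69`,
`p_feels_ill = 0.28`, the fixture's margins; `p_crp_gt_30 = 0.10`), the
outcome from a generative logistic model (default: the CRP-augmented
equation), continuous CRP from a log-normal truncated on the matching side
of 30 mg/l, and PCT / MR-proADM from log-normals with outcome-conditional
location shifts. The biomarker distribution parameters are **invented for
simulation studies** — nothing patient-level is published — and are chosen
once so that discrimination is ordered CRP > PCT > MR-proADM by
construction, mirroring the qualitative finding that CRP predicts pneumonia
best. Everything is reproducible under the spec's seed, and the generators
restore the caller's RNG state.

What the generator does *not* emulate: covariate correlation (symptoms are
independent by construction), age/vital-sign structure beyond constants,
missingness mechanisms, microbiology, antibiotic prescribing, or 30-day
outcomes. Passing simulation tests therefore demonstrate correctness of the
statistical machinery under the stated generative law, not validity of the
prediction models on real patients.

## Supporting statistics and numerical choices

* **Logistic fitting** (`fit_logistic()`): maximum likelihood via
  iteratively reweighted least squares, Wald standard errors, OR 95% CIs as
  `exp(coef ± 1.96 se)` (no profile likelihood, matching conventional
  reporting). Separation is flagged from non-convergence or |coef| > 15 on
  the logit scale and raises an error by default rather than returning
  unstable estimates. Parameter-recovery simulations at n = 500–50 000
  confirm the published coefficients are recovered within ±0.1 at the
  largest size.
* **ROC/AUC** (`roc_auc()`): threshold sweep with trapezoidal area, equal to
  the Mann–Whitney concordance probability with half credit for ties; the
  tests check this equivalence against an all-pairs brute-force count.
* **Hosmer–Lemeshow** (`hosmer_lemeshow()`): equal-size deciles of sorted
  predicted risk, tied probabilities kept together (so fewer than 10 groups
  can result), groups with zero expected counts merged with a warning,
  df = groups − 2. The published statistics (4.53 and 10.09 with df 7 and 8)
  come from the unavailable raw cohort and cannot both arise from a fixed
  10-group rule; they are not treated as reproducible targets. The df − 2
  reference is calibrated for fitted probabilities; when testing calibration
  against *known* true probabilities the statistic is closer to chi-square
  on the full group count, so the calibration tests fit the model first.
* **Nagelkerke R²** (`nagelkerke_r2()`): the rescaled likelihood-ratio
  pseudo-R², `(1 − exp(2(ll0 − ll1)/n)) / (1 − exp(2 ll0 / n))`.
* **CRB-65** (`crb65_score()`): confusion, respiratory rate ≥ 30/min,
  systolic < 90 or diastolic ≤ 60 mmHg (one point even if both pressure
  criteria hold), age ≥ 65; missing inputs are an error — no partial scores.
* **CRP bands** (`crp_band()`): < 20 mg/l rule-out, > 100 mg/l treat,
  20–100 inclusive intermediate, per the guideline wording "between 20 and
  100 mg/l".

Problem sizes in the test suite were chosen for statistical resolution:
coefficient recovery and null-coverage checks use n = 50 000 (asymptotic
standard errors ≈ 0.03, so ±0.1 is a 3σ band), calibration replicates use
n = 10 000 × 20 seeds, AUC oracle checks use n ≤ 200 where the all-pairs
loop is exact and fast.

## Worked pipeline

```{r pipeline}
fx  <- fixture_cohort()
res <- reclassify_cohort(fx, published_clinical_model(), published_crp_model())
res$table
reclassification_summary(res$table)
res$new
intermediate_to_high_summary(res$table)
decisive_fraction(res$new)
```

## Limitations

* The fixture cohort reproduces the published *counts*, not the patients:
  continuous covariates are constants, so it cannot support analyses beyond
  the indicator-based models (e.g. biomarker ROC on real distributions).
* The multivariate odds-ratio tables of the source, its Hosmer–Lemeshow and
  Nagelkerke values, and the biomarker AUCs on the real cohort require the
  undeposited raw data; the statistics are implemented and tested on
  synthetic data instead.
* PCT units are not standardised (the source never states them); values are
  stored as given.
* Complete-case analysis only, as the published table implies; no multiple
  imputation.
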