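Package: pneumorisk
Title: Pneumonia Risk Prediction and Reclassification for Acute
    Respiratory Tract Infection in Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting radiographic pneumonia (consolidation on
    chest X ray) in adult primary-care patients presenting with an acute
    respiratory tract infection. Implements two published logistic
    prediction equations (clinical signs and symptoms only, and the same
    model augmented with a C-reactive protein > 30 mg/l indicator),
    three-tier risk stratification at 2.5% and 20% predicted probability,
    category-based reclassification tables with the overall
    reclassification improvement (ORI) and net reclassification
    improvement (NRI) statistics, supporting model-evaluation statistics
    (ROC AUC, Hosmer-Lemeshow calibration, Nagelkerke pseudo R-squared,
    CRB-65 severity score, CRP guideline bands), and synthetic cohort
    generators: a deterministic 249-patient fixture cohort reconstructed
    from published reclassification counts, plus a seeded stochastic
    generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
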