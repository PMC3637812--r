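Package: screenlca
Title: Latent Class Reference Standards for Screening Colonoscopy Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies screening (versus diagnostic) colonoscopies in
    administrative health claims when no gold standard indication exists. A
    Bayesian latent class model combines three imperfect indication
    indicators (endoscopist questionnaire plus two patient-reported
    indications) into a posterior screening probability per response
    pattern, dichotomized at 50% to form a latent reference standard.
    Claims histories are reduced to binary predictors over per-category
    lookback windows; candidate classifiers (full and BIC-selected
    best-subset logistic regression, Gini recursive partitioning, and the
    El-Serag expert rule) are scored against the latent and endoscopist
    standards with sensitivity, specificity, predictive values, Cohen's
    kappa and ROC AUC. A synthetic cohort generator with known latent truth
    replaces restricted provincial claims data and makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    rpart
Config/testthat/edition: 3
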