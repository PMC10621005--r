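Package: cadimmune
Title: Immune Cell Subset Proportion Analysis for Coronary Artery Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Statistical pipeline for circulating immune-cell subset
    proportions versus coronary artery disease (CAD) status in mass-cytometry
    cohort studies: cohort characteristic tables (chi-squared, Fisher exact,
    Wilcoxon rank-sum), per-subset logistic odds ratios with age/sex
    adjustment, cross-cohort fold-change concordance, per-patient
    classifiability scoring under repeated cross-validation with AUC-screened
    lasso models, and a radial-kernel SVM immune signature with averaged ROC
    curves and a PCA decision-boundary map. Includes a logit-normal synthetic
    cohort generator that emulates the discovery/validation structure of such
    studies so the full pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
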