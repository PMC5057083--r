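Package: ratiodx
Title: Metabolite-Ratio Index Discrimination for Plasma Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for case-control biomarker discovery from annotated
    capillary-electrophoresis mass-spectrometry peak tables. Converts peak
    areas to absolute concentrations via internal standards, applies
    signal-to-noise and missingness retention rules with half-minimum
    imputation, screens metabolites by Mann-Whitney tests and linear SVM
    recursive feature elimination, builds pathway-guided metabolite-ratio
    indexes (e.g. ornithine/citrulline across ornithine transcarbamylase),
    fits a multiple logistic regression discrimination model, and validates
    it by ROC/AUC with closed-form confidence intervals, repeated stratified
    k-fold cross-validation and bootstrap resampling. Includes a synthetic
    two-cohort plasma metabolome generator so the whole workflow is testable
    without access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
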