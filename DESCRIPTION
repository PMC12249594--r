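Package: escbio
Title: Eye-Selection-Criteria Analysis for Paired-Eye Ophthalmic Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how eye selection criteria (right, left, random,
    both, best and worst eye) affect diagnostic and prognostic biomarkers built
    from paired-eye ophthalmic measurements. Includes a synthetic paired-eye
    cohort generator with configurable inter-eye correlation, construction of
    the six eye-selection-criteria datasets with selection audits, intraclass
    correlation with Koo-Li qualification and a pooling decision rule, single
    imputation (perturbed regression and k-nearest-neighbour), rank-based
    univariate comparison batteries, cutoff and ROC/AUC diagnostics with
    bootstrap and permutation inference, and Stable Sparse Biomarkers Detection:
    repeated subject-level subsampling of elastic-net models yielding
    per-variable stability indices, applied to pituitary-macroadenoma diagnosis
    and 12-month visual-recovery prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
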