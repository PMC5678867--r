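Package: ppglscore
Title: Histopathological Grading and Metastatic-Risk Validation for
    Pheochromocytoma and Paraganglioma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the three histopathological grading scores used to
    stratify metastatic potential in pheochromocytoma and paraganglioma
    (PPGL): the Grading system for Adrenal Pheochromocytoma and
    Paraganglioma (GAPP, 0-10 with WD/MD/PD differentiation classes), the
    Pheochromocytoma of the Adrenal Scaled Score (PASS, 0-20 with the
    >=4 high-risk rule), and a modified GAPP (M-GAPP) that adds loss of
    SDHB immunohistochemical staining. Provides the full statistical
    validation pipeline for such scores: contingency tests, group
    comparisons, Cox proportional-hazards association, ROC/AUC with
    DeLong comparison of correlated curves, Youden cutoff selection,
    Kaplan-Meier metastasis-free survival with log-rank tests, and
    Pearson correlation with time to metastasis. A calibrated synthetic
    cohort generator makes every pipeline stage testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
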