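Package: adrrisk
Title: Drug Risk-Level Classification from Spontaneous Adverse Drug Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies post-marketing drugs into three regulatory risk levels
    (prescription, over-the-counter A, over-the-counter B) from spontaneous
    adverse drug reaction (ADR) reports. Implements the full pipeline:
    cleaning and aggregation of spontaneous reports into a drug-by-ADR count
    table, proportional reporting ratio (PRR) disproportionality signal
    detection, Gini-importance feature ranking with top-k selection, feature
    augmentation with a generative adversarial network trained on the selected
    PRR submatrix, SMOTE minority oversampling to balance the three classes,
    and random-forest classification with a multiclass evaluation suite
    (per-class precision/recall/F1, macro and weighted averages, one-vs-rest
    ROC/AUC). Includes a seeded synthetic spontaneous-report generator that
    emulates the statistical structure of a large regional pharmacovigilance
    database, so every stage is testable without access to confidential
    reporting data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
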