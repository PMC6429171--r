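Package: methmark
Title: Discovery and Evaluation of Tissue-Specific DNA Methylation
    Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discovering tumor-specific DNA hypermethylation
    biomarkers from grouped Illumina 450K beta-value matrices and for
    evaluating them diagnostically and prognostically. Implements a
    blood-leukocyte pre-filter followed by a two-string CpG selection
    cascade (pan-cancer and prostate-cancer-specific search strings),
    reduction of quantitative methylation-specific PCR (qMSP) plates to
    normalized methylation levels under triplicate, standard-curve and
    reference-gene quality control, rank-based group comparison with ROC
    analysis, and biochemical-recurrence survival analysis (Kaplan-Meier,
    log-rank, Cox proportional hazards, Harrell's concordance, stepwise
    backward selection, multiplicity adjustment and risk-subgroup
    analysis). Ships synthetic-data generators with planted ground truth
    for every layer so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
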