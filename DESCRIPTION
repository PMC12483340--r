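Package: sevrules
Title: Stability-Selected Decision-Tree Rules for GAD-7 and PHQ-9 Severity
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Mines short, stable decision-tree rules that stratify anxiety
    (GAD-7) and depression (PHQ-9) questionnaire respondents into minimal/mild,
    moderate and severe classes. Provides a from-scratch CART classifier
    (Gini splits, minsplit/minbucket constraints, maximum depth tuned by
    stratified 10-fold cross-validation), repeated 70/30 resampling with
    root-to-leaf rule extraction and repetition counting, one-vs-rest
    screening metrics (accuracy, sensitivity, specificity, precision, F1,
    ROC-AUC) summarised as mean (SD) across repetitions, external validation
    of frozen rule sets, and a graded-response-model cohort simulator with
    demographic marginals for end-to-end reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
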