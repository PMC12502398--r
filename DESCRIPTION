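Package: bsgdiag
Title: Mutation-Methylation Co-Detection Analysis for Brainstem Glioma Liquid Biopsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for cerebrospinal-fluid ctDNA co-detection of
    driver mutations and targeted CpG methylation in brainstem glioma.
    Implements subtype-specific CpG marker discovery (rank-sum screening with a
    delta-beta cutoff and three-algorithm consensus feature selection), the
    Methylation Signature Score and Methylation Risk Score, a three-class
    random-forest methylation classifier, a mutation-methylation fusion
    diagnosis (BSGdiag), evaluation statistics (Agresti-Coull intervals,
    midrank ROC AUC with stratified bootstrap intervals, macro/micro
    multiclass AUC), risk-score survival stratification (Kaplan-Meier, Cox),
    and longitudinal minimal-residual-disease monitoring. A synthetic-cohort
    generator emulating tissue and CSF methylation, tumor-fraction dilution,
    DNA-mass detection limits, and treatment trajectories makes every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    glmnet,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
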