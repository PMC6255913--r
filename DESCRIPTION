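Package: admarker
Title: Blood Transcriptomic Biomarker Discovery and Blood-Brain
    Concordance Analysis for Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for discovering blood-based transcriptomic
    biomarkers of Alzheimer's disease and relating blood differential
    expression to the brain. Provides covariate-adjusted differential
    expression with empirical-Bayes variance moderation across merged
    microarray cohorts, Fisher-exact cross-tissue enrichment and sign-test
    direction concordance, hypergeometric gene-set overrepresentation, and
    a biomarker-panel discovery procedure based on repeated cross-validated
    LASSO feature selection followed by an SVM / random-forest / ridge
    logistic ensemble with majority voting. A synthetic-cohort generator
    with planted differential expression, covariate effects, batch offsets
    and a discriminative panel of known effect size makes every stage
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    e1071,
    randomForest,
    jsonlite
Suggests:
    limma,
    pROC,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
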