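Package: cernaforge
Title: Competing Endogenous RNA Network Inference with Co-Expression
    Modules, Diagnostic Signatures and Immune Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of a transcriptomic inference
    pipeline for case/control cohorts, motivated by the analysis of
    obstructive sleep apnea: cohort merging with linear-model batch
    removal, empirical-Bayes moderated differential expression with
    Benjamini-Hochberg control, weighted co-expression module detection
    (soft thresholding, topological overlap, tree cut, module
    eigengenes), a LASSO plus random-forest diagnostic signature with
    ROC evaluation, lncRNA-miRNA-mRNA competing endogenous RNA network
    construction with degree-based hub extraction and
    direction-consistency pruning, and single-sample gene-set enrichment
    (ssGSEA) immune-infiltration scoring. A seeded synthetic-cohort
    generator plants every structure the pipeline looks for, so the
    whole analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    limma,
    mclust,
    randomForest,
    stats,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
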