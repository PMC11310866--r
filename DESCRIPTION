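Package: emtsub
Title: Methylation-Driven EMT Subtyping of Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and classification of epithelial-mesenchymal transition
    (EMT) subtypes of breast cancer from DNA methylation. Implements moderated-t
    differential methylation filtering with Benjamini-Hochberg control, consensus
    non-negative matrix factorization (Brunet KL multiplicative updates) with
    cophenetic/dispersion rank selection, per-sample EMT state scoring (two-sample
    KS, correlation-weighted 76-gene, mean-difference signatures and a generic
    ssGSEA engine), a multi-stage machine-learning framework that derives a
    gene-panel subtype classifier (consensus differential analysis, logistic
    quality control, correlation filtering, Boruta and SVM-RFE wrappers,
    multinomial sparse-group-lasso stability selection, cross-validated model
    competition), and a ridge-regression transfer of cell-line drug response that
    nominates subtype-specific agents. A seeded synthetic-cohort generator with
    planted subtype structure exercises every stage without cohort downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    ranger,
    e1071,
    xgboost,
    jsonlite,
    fgsea,
    mclust,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    limma,
    nnet,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
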