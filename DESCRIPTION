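Package: tacesig
Title: Stability-Selected Gene Signatures for Predicting Response to
    Transarterial Chemoembolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for building transcriptomic response
    signatures for transarterial chemoembolization (TACE) in liver cancer:
    expression matrix ingestion with probe collapsing and z-scoring,
    moderated-t differential expression with Benjamini-Hochberg control,
    per-sample rank-based gene-set enrichment scoring, occurrence-based
    multi-model stability feature selection over repeated stratified
    splits, a calibrated linear support-vector signature evaluated at a
    0.5 probability threshold, survival stratification of predicted groups
    (Kaplan-Meier, log-rank, Cox, time-dependent ROC), non-negative
    least-squares cell-fraction deconvolution, and an mRNA stemness index.
    Ships a synthetic-cohort generator with planted ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
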