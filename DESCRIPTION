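Package: endomiR
Title: Plasma miRNA Biomarker Discovery and Neural-Network Classification
    for Adolescent Endometriosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase circulating-microRNA biomarker workflow for
    case-control studies with effect modification by exogenous hormone use.
    Discovery-phase qPCR statistics (technical-duplicate collapsing, Ct
    quality control, global normalization, Normfinder reference-gene
    stability, 2^-ddCt relative quantification, hormone-stratified t-tests
    and a dual-threshold candidate rule); replication-phase feature
    selection on bead-array fluorescence (log10 transform, Holm-Sidak
    step-down correction, PCA separation checks, correlation-based feature
    selection with a forced covariate); a BFGS-trained multilayer-perceptron
    ensemble sweep with test-set model selection; and ROC evaluation with
    Hanley-McNeil inference against chance. Includes a synthetic cohort
    generator that plants hormone-stratum-specific expression effects so
    the whole pipeline is testable end to end without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
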