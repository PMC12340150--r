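Package: CSFPeptidomics
Title: Discovery and Validation Workflow for CSF Peptidome Biomarkers
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for cerebrospinal-fluid (CSF) peptidomics
    biomarker studies: spike-in standard (StdPep) and total-ion-chromatogram
    normalization of peptide-by-sample abundance matrices, analytical QC
    (coefficients of variation, identification counts, abundance dynamic
    range), s0-moderated two-sample statistics with permutation-based false
    discovery rate control, Gaussian down-shift imputation of left-censored
    missing values, tryptic-like peptide classification, a multi-criteria
    candidate-selection cascade with stability and contaminant exclusion
    rules, parallel reaction monitoring (PRM) light/heavy panel
    quantification with transition-level quality control, and single- and
    combined-peptide ROC panel classification. A synthetic CSF peptidome
    generator with realistic dynamic range, technical noise and
    abundance-dependent missingness makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
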