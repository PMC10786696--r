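Package: cfgvhd
Title: Tissue-Specific Cell-Free DNA Methylation Analysis for Chronic
    Graft-Versus-Host Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies tissue-of-origin cell-free DNA (cfDNA) from targeted
    bisulfite amplicon sequencing of tissue-specific DNA methylation markers,
    expresses tissue loads in genome equivalents per milliliter plasma, and
    models chronic graft-versus-host disease (cGVHD) after hematopoietic stem
    cell transplantation. Includes marker-panel handling, a synthetic-data
    module (bisulfite amplicon reads for tissue mixtures and a synthetic
    transplant cohort), spike-in detection-limit simulation, nonparametric
    cohort statistics (Mann-Whitney, Spearman), and a
    nonnegativity-constrained logistic-regression classifier with
    Shapley-value feature ranking evaluated by repeated stratified 5-fold
    cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
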