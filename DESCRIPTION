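Package: msremip
Title: Methylation Quantification and Tumor Classification from
    MSRE-Digested smMIP Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational pipeline for targeted DNA methylation assays
    that combine methylation-sensitive restriction enzyme (MSRE) digestion
    with single-molecule molecular inversion probe (smMIP) capture
    sequencing. Provides a synthetic assay simulator (digestion, capture,
    PCR duplication, paired-end reads with dual sample barcodes and
    unique molecular identifiers), UMI-aware demultiplexing and read
    counting against a panel reference, a lambda spike-in digestion
    quality control, reference-based count normalization, an ensemble of
    univariate linear discriminant models selected by cross-validated AUC
    for tumor versus normal classification, and assay characterization
    statistics (repeatability, spike-in calibration, limits of blank and
    detection, two-sample power, qPCR delta-Ct digestion efficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
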