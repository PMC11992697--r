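Package: idrbench
Title: Disorder-Stratified Benchmarking of Variant Effect Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate variant effect predictors (VEPs) separately in
    intrinsically disordered and ordered protein regions. Converts per-residue
    disorder score tracks (AIUPred-, metapredict-, flDPnn-, AlphaFold2
    pLDDT- and RSA-style) into smoothed disorder calls and classified IDR
    segments, annotates missense variants with their disorder context and
    start-methionine attributes, thresholds continuous or categorical VEP
    outputs into pathogenic/benign calls, and estimates sensitivity and
    specificity per disorder class with a four-stratum bootstrap. Includes a
    synthetic cohort generator with known ground truth for end-to-end testing
    and parameter recovery, plus chi-square and Wilcoxon association tests for
    IDR positional groups and second-methionine distances.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
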