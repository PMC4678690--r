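Package: dhssremodel
Title: Differential Chromatin Accessibility from DNase I Hypersensitivity and CAGE Tag Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls DNase I hypersensitive site (DHSS) clusters from mapped
    5'-end tag libraries of two conditions using a two-scale sliding-window
    binomial z-score with an empirical false discovery rate cutoff calibrated
    against matched random draws, and classifies clusters as condition-induced
    with one-tailed Fisher's exact tests under Benjamini-Hochberg control.
    Also provides single-linkage CAGE transcription start site clustering with
    TPM filtering and differential calling, promoter/repeat/enhancer
    annotation and enrichment statistics, position weight matrix scanning at a
    relative-score threshold, and a seeded synthetic data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
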