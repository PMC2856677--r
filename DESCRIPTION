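Package: mpssde
Title: Differential Expression Analysis for MPSS Tag Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing massively parallel signature sequencing
    (MPSS) tag-count libraries in a two-condition design, as used to compare
    glioblastoma and normal brain transcriptomes. Provides virtual DpnII
    signature extraction and tag-to-transcript mapping with class 1-5
    annotation, stepper merging and tags-per-million quantification, a
    two-library proportion Z-test with an empirical null built from technical
    replicates and a Storey-type false discovery rate, validation statistics
    (exact 2x2 tests, Welch t-tests, comparative-Ct relative expression), an
    interaction-network overlay exporter, and a fully seeded synthetic MPSS
    data generator so every stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
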