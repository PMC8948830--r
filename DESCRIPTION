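Package: citl
Title: Time-Lagged Causal Discovery from Single-Cell Expression and RNA Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers time-lagged causal relationships between genes from
    single-cell RNA-seq data by testing conditional independence between the
    current expression level of one gene and the changing expression level
    (RNA velocity) of another (the CITL method). Includes an order-independent
    PC-stable implementation with partial-correlation Fisher-z tests, a linear
    structural simulator of time-lagged and instant regulation with
    single-trace and multi-trace designs, asynchronous-velocity distortion and
    latent-gene removal, Pearson-correlation and PC-stable comparison
    baselines, and evaluation metrics (edge and direction precision/recall/F,
    ability of determining directions, ROC/PR) with a replication harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
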