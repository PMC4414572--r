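Package: barcodelib
Title: Build and Audit DNA Barcode Reference Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and auditing DNA barcode (COI-5P)
    reference libraries from BOLD-style specimen tables: barcode data-standard
    quality control, uncorrected and Kimura 2-parameter pairwise distances,
    BIN-style OTU clustering (threshold single-linkage with Markov-clustering
    refinement), reconciliation of specimen names against a taxonomic
    checklist with synonym and spelling resolution, BIN/species concordance
    auditing, library assembly with exclusion accounting, and summary tables
    (suborder roll-ups, family coverage, concordance histograms, primer
    success). Includes a synthetic-data generator with a planted-truth ledger
    so the whole workflow is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
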