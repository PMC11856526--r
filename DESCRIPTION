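Package: surfrank
Title: Shortlisting and Rank Aggregation of Cell-Surface Therapeutic Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annotation-driven pipeline for prioritising tumour cell-surface
    antigens for immunotherapy. Implements a sequential filter chain over Human
    Protein Atlas style gene annotation tables (brain and lung expression,
    tissue distribution, tumour FPKM, subcellular localisation, blood
    detectability) with a full per-gene audit trail; a multi-dataset rank-score
    aggregation statistic that combines transcript and protein median
    expression into a weighted normalized score; single-cell QC,
    log-normalization and per-group Pearson correlation-module extraction
    around a target gene; normality-gated two- and multi-group comparison
    tests; and seed-reproducible synthetic-data generators with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
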