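Package: dtcna
Title: Nonadditivity Analysis of SAR Data via Double-Transformation Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying nonadditivity in structure-activity
    relationship (SAR) data. Implements curation of raw assay measurement
    tables into per-assay pActivity tables, matched molecular pair (MMP)
    indexing by single acyclic-bond fragmentation, assembly of
    double-transformation cycles (DTCs), the delta-delta-pActivity
    nonadditivity statistic with a propagated experimental-noise
    significance framework, per-compound additivity-shift profiles,
    nonadditivity-aware QSAR data splitting with fingerprint regression
    models, and a Free-Wilson style synthetic-library generator with
    injected pairwise interactions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    e1071,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
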