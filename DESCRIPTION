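Package: nof1seq
Title: Single-Patient RNA-Seq Profiling Against a Frozen Reference Cohort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an n-of-1 transcriptomic reporting workflow for
    breast cancer. A reference cohort of tumor and normal RNA-seq count
    profiles is reduced once to a frozen reference object (per-gene
    geometric means for median-of-ratios size factors, a background gene
    set defining an expression-reliability cutoff, negative-binomial
    normal-tissue parameters, and nearest-shrunken-centroid classifiers
    for receptor status and molecular subtype). A single new patient
    sample is then normalized, filtered, tested for differential
    expression, classified, subjected to topological pathway impact
    analysis, joined to clinical variant annotation and fusion candidate
    tables, matched against approved drugs, and rendered into an
    interactive HTML report with CSV exports and a print-ready clinical
    summary. A deterministic synthetic-data generator emulates every
    required input so the whole pipeline runs with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
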