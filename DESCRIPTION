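Package: spliceratio
Title: Junction-Based Alternative Splicing Event Classification and
    Regulated Splicing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies ten canonical alternative splicing event
    types (exon skipping, cassette exon, alternative 5'/3' splice sites and
    their exon-skipping combinations, mutually exclusive exons including
    alternative-first and alternative-last variants, and intron retention)
    from per-sample splice-junction read tables against a GTF-derived splice
    graph. Quantifies events with the AS ratio (alternative-form junction
    reads over alternative plus model-form reads), calls regulated events
    between sample groups with an effect-size threshold plus Student t-test,
    and provides the surrounding analysis layer: FPKM/CPM normalisation, a
    documented stand-in differential-expression caller, 2^-ddCT qPCR
    quantification, hypergeometric gene-set enrichment with
    Benjamini-Hochberg correction, anchor-gene coexpression screening,
    splicing-factor/event correlation networks with hub ranking, and
    expression-based sample stratification. A seeded synthetic-data
    generator plants ground-truth events, fold changes and correlation
    structure so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
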