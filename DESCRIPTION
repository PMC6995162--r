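Package: NormRank
Title: Reference-Gene Selection for High-Throughput RT-qPCR by Consensus
    Stability Ranking
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies stable endogenous reference genes (normalizers) in
    high-throughput RT-qPCR quantification-cycle (Cq) data. Implements four
    expression-stability scorers (GeNorm M, NormFinder in grouped and
    ungrouped variants, BestKeeper SD), combines them into a fractional-rank
    consensus normalization score, scores arithmetic-mean combinations of two
    and three genes by sequential dataset augmentation, aggregates rankings
    across datasets, selects a minimal reference set covering first-place
    combinations with a pairwise normalizing-affinity matrix, and validates a
    candidate set against random same-size sets by Monte-Carlo sampling.
    Includes dataset curation and inclusion gating for Cq tables and a
    synthetic qPCR data generator with planted reference genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
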