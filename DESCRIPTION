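Package: apoPistil
Title: Differential Expression, Co-Expression Networks and Annotation
    Transfer for Sexual Versus Aposporous Pistil Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for comparing sexual and aposporous
    (apomictic) Hypericum perforatum pistil transcriptomes across two
    floral stages: 75th-percentile normalisation, unpaired t-tests with
    signed fold-change thresholds and eight-way cluster assignment,
    thresholded Pearson co-expression networks with predicate-based
    sub-network extraction, hypergeometric GO over-representation with
    true-path propagation and Benjamini-Hochberg correction, principal
    coordinates ordination on Manhattan distances, BLAT top-hit quality
    filtering with genomic flank extraction for annotation transfer, and
    delta-delta-Ct / Pfaffl qPCR relative quantification. A synthetic-data
    module generates all fixture inputs with planted effects so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    igraph,
    xml2,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
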