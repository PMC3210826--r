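Package: toxarray
Title: Expression Array Analysis for Inhalation Toxicogenomics Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of the statistical pipeline used in
    inhalation toxicogenomics studies of pulmonary gene expression:
    LOWESS normalization of two-color reference-design arrays, quantile
    normalization and negative-control present calls for single-channel
    arrays, gene-wise differential expression with a shrinkage F (Fs)
    statistic and residual-shuffling permutation p-values, two
    correlation-tolerant gene-set enrichment tests (rank-based and
    design-based bootstrap), comparative-Ct relative quantification for
    PCR arrays with a REST-style randomization test, and inhalation
    deposited-dose arithmetic. A built-in synthetic-data generator with
    known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Microarray, GeneSetEnrichment, Normalization,
    DifferentialExpression, qPCR
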