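Package: memorydiff
Title: Comparative Brain-Transcriptomics of Insect Memory Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, strand-aware comparative transcriptomics
    pipeline for contrasting long-term memory (LTM) against
    anesthesia-resistant memory (ARM) conditioning in parasitic wasps.
    Provides structural annotation of de novo transcriptomes (sense,
    antisense-to-protein, antisense-to-sense, lncRNA, unknown, with
    UTR-zone assignment of antisense transcripts), a counts-per-million
    low-support filter, negative-binomial GLM differential expression
    with replicate blocking and trended dispersion, a three-rule
    LTM-versus-ARM candidate-gene framework with splice-variant
    discrimination, Fisher-exact GO-slim term enrichment, and a
    synthetic-data generator that plants ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
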