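Package: stromasig
Title: Integrated Gene and miRNA Expression Analysis of Activated Fibroblasts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for characterizing activated stromal
    fibroblasts from paired microarray designs: detection-based probe
    filtering and probe-to-gene collapsing, paired differential expression
    with empirical-Bayes variance moderation, pre-ranked running-sum gene
    set enrichment with permutation significance and leading-edge
    extraction, centroid-signature scoring of external datasets, miRNA-set
    enrichment with coherence calling, miRNA-correlation-guided gene
    enrichment, and delta-delta-Ct qPCR relative quantification. Includes a
    synthetic-cohort generator with known ground truth emulating a paired
    3-patient by 4-condition fibroblast study, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
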