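Package: fibromiR
Title: Fibrosis Scoring and miRNome Analysis of Dystrophic Muscle and Muscle Progenitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for linking the small-RNA transcriptome of
    dystrophic skeletal muscle to its fibrotic status. Computes a composite
    fibrotic score from three marker genes (COL1A1, FN1, ACTA2), stratifies
    biopsies into low- and high-fibrotic subsets, performs per-miRNA
    negative-binomial exact tests with Benjamini-Hochberg correction,
    selects a fibrosis-correlated miRNA signature, clusters samples and
    miRNAs with Pearson-correlation distance and complete linkage,
    classifies fibro-adipogenic versus myogenic progenitor miRNA profiles
    under TGFbeta1 into four archetypes, quantifies qPCR data by the
    comparative-CT method, and scans 3'UTR sequences for canonical miRNA
    seed-match sites. Includes seeded synthetic-data generators with known
    planted structure so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
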