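Package: cisreg
Title: Motif Scanning, ChIP-Peak Enrichment, Spacing-Constraint Tests, and
    Two-Tissue Co-Expression Modules
Version: 0.1.0
Authors@R: person("Regulatory", "Genomics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A toolkit for regulatory-genomics analyses around a transcription
    factor's ChIP peaks: position weight matrix construction from IUPAC
    consensus strings or count matrices, Patser-style score-threshold
    calibration from the exact background score distribution, double-stranded
    sequence scanning, motif enrichment in peaks against length-matched random
    genomic background (Fisher exact), a shuffle-null permutation test for
    constraints on inter-site spacing of heterotypic motif pairs,
    class-differential motif association, hypergeometric gene-list overlap and
    fold-change concordance statistics, attenuation (epistasis-style) binomial
    tests, peak-to-gene assignment within a distance window, per-peak
    differential-binding ANOVA, and a two-tissue coherent co-expression module
    pipeline (WGCNA-style modules, resampled tight clusters, cross-tissue
    coherent clusters). A synthetic-data module generates sequences with
    planted motifs and fixed-spacing motif pairs, correlated differential
    expression tables, and paired two-tissue expression matrices with planted
    latent-factor modules, so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
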