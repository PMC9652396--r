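Package: chromage
Title: Age-Dependent Chromatin Accessibility and Heterochromatin Decay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting age-dependent chromatin accessibility changes
    from single-nucleus ATAC-seq pseudo-bulk counts and relating them to
    heterochromatin biology. Implements negative-binomial likelihood-ratio
    differential testing with tagwise dispersion shrinkage, TSS-enrichment
    quality control with Tn5 insertion-site correction, exact-depth read
    down-sampling, weighted-Pearson gene-cCRE linking with rank-sum
    concordance testing, Gaussian-kernel detection of megabase-scale clusters
    of age-differential cCREs, broad heterochromatin (H3K9me3) domain calling,
    per-domain differential statistics, per-cell fraction-of-reads-in-domain
    summaries, and interval overlap enrichment tests. Ships a seeded
    synthetic-data generator with planted age effects, clustered age-up cCREs
    inside decaying heterochromatin domains, and latently coupled RNA, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
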