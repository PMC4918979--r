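Package: bivalentSmad
Title: Smad2/3 ChIP-Seq Targets and Bivalent Chromatin Resolution in
    Osteoclast Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative ChIP-seq and expression-microarray pipeline for
    identifying TGF-beta-Smad2/3 target genes in bone-marrow-derived
    macrophages whose H3K4me3/H3K27me3 bivalent promoter state resolves to
    H3K4me3-only upon TGF-beta, and whose expression is TGF-beta-induced and
    RANKL-repressed. Provides signal-ratio peak calling on binned read
    coverage, TSS-window peak-to-gene assignment, chromatin-state transition
    classification, expression filtering and fold-change categories,
    fold-enrichment/chi-square and GSEA running-score statistics with
    permutation p-values, TSS metaprofiles, and a seeded synthetic-data
    generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    GenomeInfoDb,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    fgsea,
    optparse,
    knitr
Config/testthat/edition: 3
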