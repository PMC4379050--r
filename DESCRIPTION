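Package: broilertx
Title: Two-Line Broiler Breast-Muscle Transcriptome Comparison Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, fully seedable pipeline for comparing bulk RNA-seq
    transcriptomes between two chicken lines (a modern commercial broiler and
    a legacy line) at two post-hatch ages. Implements RPKM quantification with
    an expression filter, a fold-change-outlier differential-enrichment rule
    (per-day log2 RPKM ratio between lines flagged beyond k standard
    deviations from the mean ratio together with a per-gene p-value
    threshold), cross-line concordance fits and hierarchical clustering of
    enriched genes, GO-slim term tallies from a local annotation map,
    delta-delta Ct and standard-curve qPCR quantification, a negative-binomial
    synthetic-data generator emulating the two-line two-day design, and a
    simulation-based replicate/depth power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    optparse
Config/testthat/edition: 3
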