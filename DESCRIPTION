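Package: popcnv
Title: Population-Based Copy Number Variant Detection from Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects copy number variants (CNVs) from whole-genome
    sequencing read depth by comparing each sample against a panel of
    reference samples. The genome is tiled into fixed-size bins, reads are
    counted and GC-corrected, and each bin is normalized against a set of
    "supporting" bins with a similar coverage profile across the reference
    panel (targeted normalization). Bins are then tested with Z-scores and
    a false discovery rate threshold, and abnormal bins are merged into
    deletion and duplication calls with copy-number estimates. The package
    also provides coverage QC diagnostics, cohort CNV catalog construction
    with rare-frequency annotation against structural-variant databases,
    burden and enrichment permutation tests, and a synthetic coverage
    simulator with spiked CNVs for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    limma
Suggests:
    optparse,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
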