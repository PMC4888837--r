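Package: damidscope
Title: DamID-Seq Peak Calling and Co-Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of DamID-seq chromatin profiling experiments. Builds a
    GATC fragment model of a genome, filters aligned reads to GATC-anchored
    unique alignments (retaining duplicates), normalizes per-cut-site counts
    to reads per ten million, and calls variable-width enriched regions
    against a Dam-GFP background control using deterministic normalized-read
    and fold-over-control thresholds. Downstream tools compare peak sets
    between factors (merged-cluster Venn counts), assign peaks to promoter
    windows, compute TSS-relative peak-density metaprofiles, and measure
    misregulated-gene overlap and direction concordance between knockdown
    differential-expression tables. A self-contained simulator generates
    genomes, read libraries and correlated expression tables with known
    ground truth for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
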