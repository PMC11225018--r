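Package: rloopkit
Title: Strand-Specific R-Loop Sequencing Analysis with Spike-In Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for strand-specific R-loop mapping data (ssDRIP-seq and
    its ultra-low-input variant). Partitions paired-end fragments into
    Watson (wR-loop) and Crick (cR-loop) strand sets, builds RPGC-normalized
    coverage tracks, computes spike-in quantitative factors and relative
    total R-loop levels, profiles GC/AT skew in sliding windows and around
    region sets, calls strand-aware peaks with a minimum-size filter,
    diagnoses nuclease boundary behavior against restriction cut sites,
    measures compartment read fractions, tests region-overlap enrichment by
    permutation, and clusters stage-wise R-loop dynamics with fuzzy c-means.
    A synthetic-data generator plants strand-specific skewed R-loop regions
    and simulates fragment libraries (including spike-in pairs and
    RNase-H-style null libraries) so every stage is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
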