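Package: puracn
Title: Tumor Purity and Absolute Copy Number Inference from Read Depths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers tumor purity from the read depths of copy-number-loss
    regions in an admixed tumor-normal sequencing sample, using a non-linear
    mixture model solved by exhaustive grid search, and converts observed
    read depths of all copy-number-variant regions into absolute copy
    numbers. Includes a binned, GC-corrected read-depth profiler for BAM
    input, a simplified anomaly-score CNV detector (one-dimensional
    isolation forest scores smoothed by total variation and tested against
    a fitted Gamma distribution), and a synthetic admixed-profile generator
    with known purity and planted integer copy numbers for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, Sequencing, Coverage, SomaticMutation
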