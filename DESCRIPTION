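Package: moRfinder
Title: Discovery and Quantification of microRNA-Offset RNAs from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale small RNA-seq pipeline for the discovery and
    quantification of microRNA-offset RNAs (moRNAs), the short RNAs produced
    immediately 5' and 3' of microRNA hairpin precursors. Implements FASTQ
    quality filtering and adapter trimming, ungapped mismatch-tolerant
    multi-locus read alignment, a hierarchical ncRNA annotation cascade,
    mature miRNA counting with locus extension, isomoR grouping with
    most-abundant-isoform reference selection, moRNA quantification and
    descriptive statistics (arm usage, length distributions, 5'-end
    consistency, miR-moR correlation), novel minor-arm miRNA calling,
    post-prediction filters for novel hairpin candidates with conservation
    classification, 7-mer seed-match target cross-tabulation, and a fully
    deterministic synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
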