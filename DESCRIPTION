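Package: plantmir
Title: Plant MicroRNA Discovery from Small RNA Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies novel plant microRNAs from small RNA sequencing data.
    Reads are adapter-trimmed, length- and quality-filtered, collapsed into
    unique sequences with copy counts, and mapped to the reference genome
    without mismatches.  Candidate precursor windows are excised around the
    highest-expressed read of each cluster, folded with a nearest-neighbor
    thermodynamic model restricted to single-hairpin structures, and filtered
    with plant-adapted structural rules (long precursor spans, minimum
    terminal-loop size, strict read-consistency over the mature/star duplex).
    Surviving candidates receive an additive log-odds score; predictions are
    reported as tab-separated tables and hairpin-with-reads diagrams (text and
    SVG).  A synthetic-data module plants stem-loop precursors in random
    genomes and simulates reads for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    Rsamtools,
    Rcpp,
    xml2,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
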