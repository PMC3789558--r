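Package: helitronscan
Title: Structure-Based Discovery and Evolutionary Analysis of Helitron
    Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide identification of Helitron rolling-circle
    transposons from their terminal sequence structure (5' TC dinucleotide,
    subterminal hairpin, 3' CTRR motif followed by the host T), followed by
    greedy clustering of end windows, center-star consensus building with
    automated element-boundary calling, a seeded-alignment copy census with
    intact/fragment classification, Kimura 2-parameter insertion dating,
    mismatch-distribution burst analysis, neighbor-joining trees, gene-capture
    and transcript-contribution calling, and a synthetic-genome simulator with
    planted families for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
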