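Package: snrcm
Title: Single Long-Read Cluster Mining from Simulated Fosmid Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico workbench for recovering complete biosynthetic gene
    clusters (BGCs) from pooled metagenomic fosmid libraries. Simulates a
    soil-metagenome fosmid library (pooled clones, Nanopore-like long reads,
    paired short reads) with planted BGC ground truth; decides per candidate
    BGC whether it is completely captured on a single long read (and hence on
    a single fosmid) by k-mer seeded, chained, band-limited alignment;
    annotates lasso peptide BGCs with a rule set over gene sizes, BLAST-style
    descriptions and domain tags, including leader/core precursor scanning;
    models serial-dilution PCR recovery of a single clone from a pool of 2000;
    and plans multi-fosmid tiling assembly of oversized clusters with
    restriction-digest prediction and size-filtered read verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
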