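Package: erosionkit
Title: Genomic Erosion Analysis for Collapsed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify genomic erosion in bottlenecked, inbred
    populations and contrast them with stable relatives: a forward-in-time
    diploid Wright-Fisher simulator with selection, dominance, selfing and
    recombination over a small annotated genome; a multi-sample variant
    filter cascade with an exact Hardy-Weinberg test; windowed nucleotide
    diversity, regional heterozygosity, site frequency spectra and Tajima's D;
    zero-fold/four-fold degenerate site classification; runs-of-homozygosity
    calling and FROH; linkage-disequilibrium decay and its half-maximum
    distance; and outgroup-polarized genetic-load accounting over
    synonymous, tolerated, deleterious and loss-of-function variant classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
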