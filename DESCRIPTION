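Package: splicealigner
Title: Spliced Protein-to-Genome Alignment with Frameshift and Intron Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maps protein sequences to a nucleotide genome with explicit gene
    structure: a reduced amino-acid alphabet k-mer index over six-frame open
    reading frames with invertible-hash sampling, two-round colinear anchor
    chaining with a binned gap geometry and logarithmic gap penalties, and a
    six-state dynamic program that jointly models affine gaps, frameshifts and
    Phase-0/1/2 introns with explicit donor/acceptor splice-signal costs.
    Alignments are emitted as GFF3 gene models or PAF records with an extended
    CIGAR; a processed-pseudogene control re-scores alignments without introns
    and penalises single-exon hits. Includes an annotation-accuracy evaluator
    (confirmed splice junctions, base-level sensitivity/specificity) and a
    synthetic-locus generator used as test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
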