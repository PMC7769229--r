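Package: flatpeach
Title: Inversion Breakpoint Genotyping and Association Analysis for a
    Fruit-Shape Locus
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying a large chromosomal inversion that
    co-segregates with the flat-fruit trait in peach. The package builds
    wild (H1) and inverted (H2) haplotype models carrying the inversion's
    breakpoint indel signature (an ACA deletion at the proximal breakpoint
    and a GA insertion at the distal breakpoint), constructs breakpoint
    junction references, classifies sequencing reads as junction-spanning
    evidence with a compiled seed-and-extend aligner, calls diploid
    inversion genotypes from read support or in-silico PCR band patterns,
    refines breakpoint coordinates from split long reads, tests Mendelian
    segregation and SNP allele-frequency association (Fisher exact with
    Benjamini-Hochberg FDR), and screens expression matrices for activated
    candidate genes via TPM normalization and fold-change filtering.
    Seeded simulators generate references, F1 crosses, short and long
    reads, SNP panels and negative-binomial expression counts for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
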