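Package: mosaicamp
Title: Somatic Mosaic Variant Detection from Ultra-Deep Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting low-level somatic mosaicism
    from ultra-deep targeted amplicon sequencing, as used to localize
    activating G-protein mutations in vascular malformations. Provides
    barcode demultiplexing, an exact gapless amplicon aligner with
    read-cleaning predicates, per-locus base-count pileups, mutant-allele
    frequency estimation with a locally estimated error model and a binomial
    positivity test, an exome-style candidate calling rule with an
    affected-versus-unaffected filtration cascade, an optional protein
    salt-bridge stage for interface mutations, and a synthetic read/variant
    generator with ground-truth records so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
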