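Package: telotape
Title: Ploidy-Agnostic Telomere Length Estimation from Paired-End Whole-Genome Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates mean telomere length in base pairs from paired-end
    whole-genome sequencing alignments without assuming a chromosome count.
    Candidate telomeric read pairs are subset from a BAM file (a TELBAM),
    sequencing error is modelled from the joint distribution of Phred scores
    and mismatches against the telomeric repeat, read pairs are classified
    into telomere-internal, boundary and interstitial categories, and the
    ratio of internal to boundary pairs is inverted into a length estimate
    by Monte-Carlo fragment-placement simulation. Includes cohort-level
    correction of boundary counts, platform batch correction, and a
    synthetic paired-end data generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Rsamtools,
    Biostrings,
    S4Vectors,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, WholeGenome, Coverage, Software
RoxygenNote: 7.3.3
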