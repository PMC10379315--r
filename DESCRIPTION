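Package: elatyper
Title: Expressed Equine MHC Genotyping from Multiplexed Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A MiSeq-style amplicon genotyping pipeline for the expressed
    equine Major Histocompatibility Complex (ELA). Demultiplexes MID-tagged
    paired-end reads, merges read pairs by overlap, assigns and trims
    locus-specific primers, collapses inserts into candidate alleles with
    artifact removal, applies a read-frequency threshold of resolution with a
    cohort-wide allele recovery loop, assigns IPD-style allele names by
    amino-acid distance, infers MHCI and MHCII haplotypes from recurrent
    co-segregation of alleles across animals, and computes cohort summaries
    (standard versus universal alleles, haplotype variant families,
    locus read proportions, and MHCI-MHCII linkage). Includes a sequencing
    simulator with PCR pool ratios, expression-weighted read fractions,
    primer-mismatch allele dropout and substitution error, providing ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
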