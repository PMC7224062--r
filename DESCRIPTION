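Package: pkdpanel
Title: Pseudogene-Aware Amplicon Sequencing Analysis for ADPKD Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis toolkit for long-range-PCR amplicon resequencing of
    duplicated disease loci such as PKD1, whose six high-identity pseudogenes defeat
    conventional read mapping. Provides a synthetic-locus and read simulator with
    semiconductor-sequencing error profiles, masked-reference banded local alignment
    with mapping-confidence filtering, VAF-threshold germline calling with
    allele-balance and sequence-context quality control, binomial sub-threshold
    mosaicism scanning, allele-dropout detection across overlapping amplicons,
    MLPA-style dosage-quotient calling of exon deletions and duplications, a
    deterministic ACMG-style variant classification rule engine with hypomorphic
    alleles, trio phase and segregation categorization, and cohort-level diagnostic
    yield, concordance and genotype-phenotype statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    VariantAnnotation,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
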