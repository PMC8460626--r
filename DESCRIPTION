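Package: msatkin
Title: Microsatellite Diversity, Marker Informativeness and Exclusion-Based
    Parentage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for evaluating panels of tri- and tetra-nucleotide
    microsatellite markers and applying them to parentage and population
    questions in wild bird populations. Implements per-locus diversity
    statistics (observed and unbiased expected heterozygosity, exact
    Hardy-Weinberg tests by enumeration or Monte-Carlo, Weir-Cockerham
    F-statistics, rarefied allelic richness), marker-informativeness measures
    (polymorphic information content, probabilities of identity, parent
    non-exclusion probabilities by exact enumeration), Mendelian trio checks
    and exclusion-based detection of extra-pair paternity in full families,
    a desk-scale tandem-repeat discovery and primer-screening stage for
    FASTA input, and a seeded simulator of genotype datasets, pedigrees and
    repeat-bearing sequences. Ships the published genotypes of three
    European Robin (Erithacus rubecula) families as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
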