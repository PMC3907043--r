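Package: macgpcr
Title: Comparative Polymorphism Analysis of Macaque GPCR Resequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for targeted resequencing of G-protein coupled
    receptor (GPCR) genes in rhesus and cynomolgus macaque cohorts. Annotates
    coding consequences of variants against gene models, computes
    per-population allele counts, singleton/common classification, site
    frequency spectra and population-sharing partitions, transfers human
    secondary-structure domain annotations onto macaque orthologs through
    protein alignment to obtain per-domain polymorphism and divergence
    densities, aggregates external functional-prediction calls into a
    five-category consensus, detects cross-species recurrent mutations, and
    simulates complete synthetic cohorts with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
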