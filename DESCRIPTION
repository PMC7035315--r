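Package: mutload
Title: Deleterious Mutation Load, Genetic Purging and Reintroduction
    Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify deleterious mutation load in serially
    bottlenecked wild populations and to model its evolution through a
    reintroduction program. Classifies biallelic SNPs into functional
    impact and phylogenetic-conservation categories, applies
    variant-calling hard filters, polarizes derived alleles against
    outgroup species, and computes category-stratified site frequency
    spectra, per-individual derived allele and homozygote counts, the
    Rxy relative derived-allele statistic with intergenic
    standardization and chromosome jackknife, nucleotide diversity,
    window-based runs of homozygosity and F_ROH, and downsampling
    replicates. Includes an individual-based forward simulator of
    diploid populations under gamma-distributed selection coefficients,
    an exponential dominance-selection map, hard viability selection
    and a configurable multi-patch founding demography, plus a
    synthetic-data generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
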