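Package: kaspdx
Title: Design, Call and Validate KASP SNP Diagnostic Assays for Cryptic
    Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and running Kompetitive Allele-Specific PCR
    (KASP) diagnostics that assign individuals of a cryptic species complex
    to genome-wide SNP-defined populations. Discovers diagnostic SNPs (fixed
    homozygous differences, including scope-restricted markers) from a
    labelled genotype matrix, extracts assay-submission flanking sequences,
    builds a hierarchical decision key, calls bi-allelic genotypes from
    endpoint FAM/HEX fluorescence plates with no-template-control and
    cluster-quality gating, classifies samples through the decision key with
    fallback and confirmation markers, and reports concordance against a
    reference genotyping method. Ships the six-haplogroup panel for
    cassava-colonising Bemisia tabaci together with published validation
    summaries, and a synthetic-data generator so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
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
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
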