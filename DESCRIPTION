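Package: blastocall
Title: Single-Cell Genotyping, Allelic Dropout and Gene-Conversion Tract
    Analysis for CRISPR-Edited Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess CRISPR/Cas9 on-target editing outcomes in
    single cells of preimplantation embryos from amplicon allele-depth
    evidence. Implements coverage-threshold genotype calling with
    FreeBayes-style record filters, an on-target edit taxonomy (wild type,
    point mutant, indel, large deletion, homology-directed repair),
    embryo mosaicism labelling, sample- and locus-level allelic-dropout
    (ADO) estimation from a heterozygous-locus panel, loss-of-heterozygosity
    segment detection with interallelic gene-conversion tract bounds and
    template-parent assignment, cohort frequency tables with one-tailed
    Fisher exact comparisons, and a synthetic-data generator that simulates
    mosaic edited embryos and whole-genome-amplification artifacts with
    known ground truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
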