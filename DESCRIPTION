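Package: clonetrace
Title: Multi-Sample Clonal Evolution Analysis of Tumor Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the clonal evolution of a tumor from longitudinal or
    multi-region somatic variant calls and allele-specific copy-number
    segments. Converts observed allele counts into purity- and
    copy-number-corrected cancer cell fractions (CCF), clusters SNVs across
    samples with a binomial-emission Dirichlet-process mixture (collapsed
    Gibbs sampling), calls ploidy, whole-genome doubling, LOH, arm-level and
    focal copy-number events, builds a constrained clone tree with CNA
    precedence, and times events across dated samples. Includes a synthetic
    patient simulator that emits the same VCF/segment/panel formats the
    pipeline consumes, with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    vcfR,
    ggplot2,
    generics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
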