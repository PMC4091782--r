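Package: eftlandscape
Title: Genomic Landscape Analysis of Ewing Sarcoma Family Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational procedures used in genomic-landscape
    surveys of the Ewing sarcoma family of tumors (EFT): somatic variant
    filtering against a panel of normals and somatic-score cutoff calibration,
    structural-variant junction filtering and copy-number segment confidence
    classification, coverage-ratio copy-number calling from targeted
    sequencing, exon-level RPKM z-score detection of expression loss and
    contiguous-exon dropout, allele-specific expression classification,
    gene-fusion reading-frame annotation with TET-ETS subtype labelling, and
    multi-evidence cohort integration (oncoprint alteration matrices,
    mutational frequencies, union coverage, mutual exclusivity, and Fisher
    exact enrichment). Includes a fully parameterised synthetic cohort
    generator that emulates the statistical structure of an EFT sequencing
    cohort so that every stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    withr,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
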