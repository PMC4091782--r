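#' Synthetic published-cohort findings sheet
#'
#' Loads the shipped synthetic per-sample findings table for a
#' 101-sample EFT cohort (65 tumours, 36 cell lines, 4 of which were
#' assayed only for STAG2). The per-sample assignments are constructed so
#' that the cohort-level marginal counts match the mutational frequencies
#' reported for EFT: STAG2 altered in 14/65 tumours (21.5%) and 16/36
#' cell lines (44.4%), TP53 in 4/65 and 23/32, CDKN2A in 9/65 and 16/32,
#' and STAG2/TP53/CDKN2A altered in 57/97 fully assayed fusion-positive
#' samples (58.7%).
#'
#' @return A list with `sample_sheet` and `findings` tibbles.
#' @export
synthetic_cohort_findings <- function() {
  dir <- system.file("extdata", package = "eftlandscape")
  list(
    sample_sheet = readr::read_tsv(
      file.path(dir, "cohort_sheet_synthetic.tsv"),
      col_types = readr::cols(sample_id = "c", class = "c",
                              fusion_positive = "l", assays = "c")),
    findings = readr::read_tsv(
      file.path(dir, "cohort_findings_synthetic.tsv"),
      col_types = readr::cols(sample_id = "c", gene = "c", evidence = "c"))
  )
}

#' Alteration matrix of the synthetic published-cohort findings
#'
#' Builds the [synthetic_cohort_findings()] sheet into an
#' `eft_alteration_matrix`, routing each evidence label through the
#' corresponding evidence stream.
#'
#' @return An `eft_alteration_matrix`.
#' @export
synthetic_findings_matrix <- function() {
  fx <- synthetic_cohort_findings()
  f <- fx$findings
  mut <- filter(f, .data$evidence %in% c("truncating_mutation",
                                         "point_mutation")) |>
    mutate(consequence = ifelse(.data$evidence == "truncating_mutation",
                                "nonsense", "missense"))
  cnv <- filter(f, .data$evidence %in% c("homozygous_deletion",
                                         "intragenic_duplication")) |>
    mutate(call = .data$evidence)
  expr <- filter(f, .data$evidence == "expression_loss") |>
    mutate(flagged = TRUE)
  build_alteration_matrix(
    sample_sheet = fx$sample_sheet,
    variants = select(mut, "sample_id", "gene", "consequence"),
    cnv_calls = select(cnv, "sample_id", "gene", "call"),
    expression_loss = select(expr, "sample_id", "gene", "flagged")
  )
}
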