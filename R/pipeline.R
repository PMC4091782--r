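#' Exon z-scores for a cohort bundle
#'
#' Convenience wrapper: computes `log2(RPKM + 1)` exon values for the
#' cohort and its normal reference panel (dropping the off-panel
#' background bucket) and standardises against the panel.
#'
#' @param cohort An [simulate_cohort()] result.
#' @return Exon z-score tibble (see [exon_zscores()]).
#' @export
cohort_exon_zscores <- function(cohort) {
  prep <- function(x) {
    x |>
      filter(.data$gene != "__other__") |>
      add_exon_rpkm() |>
      select("gene", "exon", "sample_id", "log2_rpkm")
  }
  exon_zscores(prep(cohort$exon_counts), prep(cohort$panel_exon_counts))
}

#' Run the full analysis cascade on a cohort bundle
#'
#' Applies, in order: panel-of-normals artifact removal, somatic-score
#' filtering, the rare protein-altering consequence filter; coverage-ratio
#' CNV calling; exon z-scoring against the normal panel with
#' expression-loss and contiguous-exon-loss detection; fusion frame and
#' subtype annotation (fusion-positive status = any TET-ETS subtype);
#' and finally multi-evidence integration into an alteration matrix.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param score_cutoff Somatic-score cutoff (default 3, the calibrated
#'   operating point).
#' @param af_threshold Population allele-frequency threshold (default
#'   0.005).
#' @param loss_genes Genes assessed for expression loss (default STAG2,
#'   TP53, CDKN2A).
#' @return A list with `variants` (filtered), `cnv`, `zscores`,
#'   `expression_loss`, `exon_loss_runs`, `fusions` (annotated),
#'   `sample_status`, and `matrix` (an `eft_alteration_matrix`).
#' @export
analyze_cohort <- function(cohort, score_cutoff = 3, af_threshold = 0.005,
                           loss_genes = c("STAG2", "TP53", "CDKN2A")) {
  stopifnot(inherits(cohort, "eft_cohort"))

  variants <- cohort$variants |>
    remove_panel_of_normals(cohort$pon) |>
    filter_by_somatic_score(cutoff = score_cutoff) |>
    rare_coding_filter(af_threshold = af_threshold)

  cnv <- cohort$coverage |>
    exon_coverage_ratio() |>
    call_coverage_cnv()

  z <- cohort_exon_zscores(cohort)
  expression_loss <- bind_rows(lapply(loss_genes, function(g) {
    mut_ref <- unique(variants$sample_id[
      variants$gene == g &
        variants$consequence %in% c("nonsense", "frameshift", "splice_site")])
    call_expression_loss(z, g, mutant_reference = mut_ref) |>
      mutate(gene = g)
  }))
  exon_loss_runs <- detect_contiguous_exon_loss(z)

  fusions <- cohort$fusions |>
    annotate_fusion_frame(transcript_models()) |>
    classify_fusion_subtype()
  tet_ets <- fusions$sample_id[fusions$subtype != "non-TET-ETS"]
  sample_status <- cohort$sample_sheet |>
    mutate(fusion_positive = .data$sample_id %in% tet_ets)

  matrix <- build_alteration_matrix(
    sample_sheet = sample_status,
    variants = variants,
    cnv_calls = cnv,
    expression_loss = select(expression_loss, "sample_id", "gene", "flagged")
  )

  list(variants = variants, cnv = cnv, zscores = z,
       expression_loss = expression_loss, exon_loss_runs = exon_loss_runs,
       fusions = fusions, sample_status = sample_status, matrix = matrix)
}
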