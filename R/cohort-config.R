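#' Synthetic cohort configuration
#'
#' Parameters of the synthetic EFT cohort generator. Defaults encode the
#' cohort structure the downstream callers assume: a coding somatic burden
#' of ~6 mutations over 40 Mb (0.15/Mb), targeted sequencing at a mean
#' depth of 311x, a 63-sample normal-tissue expression reference panel,
#' STAG2 truncation with nonsense-mediated decay of the mutant transcript,
#' CDKN2A homozygous-deletion dropout, skewed mutant-allele RNA expression
#' diluted by admixed normal tissue, and a TET-ETS fusion-negative
#' minority with a distinct expression profile.
#'
#' @param n_tumors,n_cell_lines Sample counts per class.
#' @param n_normal_panel Normal-tissue reference panel size (default 63).
#' @param coding_target_bp Coding target space in bp (default 4e7).
#' @param mean_coding_mutations Expected somatic coding mutations per
#'   sample (default 6; drivers are drawn within this budget).
#' @param stag2_truncating_fraction,stag2_duplication_fraction,
#'   stag2_exon_deletion_fraction,stag2_expression_loss_fraction
#'   Per-sample probabilities of the STAG2 alteration classes (truncating
#'   mutation; intragenic duplication; multi-exon deletion with contiguous
#'   exon expression loss; whole-gene expression loss without an
#'   identifiable mutation).
#' @param cdkn2a_deletion_fraction Probability of CDKN2A homozygous
#'   deletion.
#' @param tp53_mutation_fraction Probability of a TP53 mutation.
#' @param brca2_k3326x_fraction Probability of carrying the BRCA2 K3326X
#'   stop polymorphism.
#' @param fusion_negative_fraction Probability that a tumour lacks a
#'   TET-ETS fusion (cell lines are always fusion-positive).
#' @param nmd_factor Multiplicative transcript retention of a truncated
#'   allele under nonsense-mediated decay, in (0, 1].
#' @param contamination_fraction Normal-cell fraction per tumour, in
#'   \[0, 1); cell lines are pure.
#' @param mean_target_coverage Mean targeted-sequencing depth (default
#'   311).
#' @param library_size Total mapped RNA reads per sample (default 2e7).
#' @param true_score_mean,artifact_score_mean,score_sd Somatic-score
#'   distribution of true calls vs platform artifacts (partially
#'   overlapping normals).
#' @param artifact_mean_per_sample Expected artifact calls per sample,
#'   drawn from a shared panel-of-normals site pool.
#' @param seed Integer seed; fully determines all generator output.
#' @return An object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_tumors = 40,
                          n_cell_lines = 10,
                          n_normal_panel = 63,
                          coding_target_bp = 4e7,
                          mean_coding_mutations = 6,
                          stag2_truncating_fraction = 0.30,
                          stag2_duplication_fraction = 0.05,
                          stag2_exon_deletion_fraction = 0.05,
                          stag2_expression_loss_fraction = 0.07,
                          cdkn2a_deletion_fraction = 0.25,
                          tp53_mutation_fraction = 0.28,
                          brca2_k3326x_fraction = 0.07,
                          fusion_negative_fraction = 0.10,
                          nmd_factor = 0.25,
                          contamination_fraction = 0.20,
                          mean_target_coverage = 311,
                          library_size = 2e7,
                          true_score_mean = 8,
                          artifact_score_mean = -2,
                          score_sd = 3,
                          seed = 1L) {
  check_count(n_tumors, "n_tumors")
  check_count(n_cell_lines, "n_cell_lines", positive = FALSE)
  check_count(n_normal_panel, "n_normal_panel")
  if (!is.numeric(coding_target_bp) || coding_target_bp <= 0) {
    abort("`coding_target_bp` must be positive")
  }
  if (!is.numeric(mean_coding_mutations) || mean_coding_mutations < 0) {
    abort("`mean_coding_mutations` must be non-negative")
  }
  for (f in c("stag2_truncating_fraction", "stag2_duplication_fraction",
              "stag2_exon_deletion_fraction",
              "stag2_expression_loss_fraction",
              "cdkn2a_deletion_fraction", "tp53_mutation_fraction",
              "brca2_k3326x_fraction", "fusion_negative_fraction")) {
    check_fraction(get(f), f)
  }
  stag2_total <- stag2_truncating_fraction + stag2_duplication_fraction +
    stag2_exon_deletion_fraction + stag2_expression_loss_fraction
  if (stag2_total > 1) {
    abort("`stag2_*_fraction` values must sum to at most 1")
  }
  if (!is.numeric(nmd_factor) || nmd_factor <= 0 || nmd_factor > 1) {
    abort("`nmd_factor` must lie in (0, 1]")
  }
  if (!is.numeric(contamination_fraction) || contamination_fraction < 0 ||
      contamination_fraction >= 1) {
    abort("`contamination_fraction` must lie in [0, 1)")
  }
  if (!is.numeric(mean_target_coverage) || mean_target_coverage <= 0) {
    abort("`mean_target_coverage` must be positive")
  }
  check_count(library_size, "library_size")
  if (!is.numeric(score_sd) || score_sd <= 0) {
    abort("`score_sd` must be positive")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer")
  }

  structure(
    list(
      n_tumors = as.integer(n_tumors),
      n_cell_lines = as.integer(n_cell_lines),
      n_normal_panel = as.integer(n_normal_panel),
      coding_target_bp = coding_target_bp,
      mean_coding_mutations = mean_coding_mutations,
      stag2_truncating_fraction = stag2_truncating_fraction,
      stag2_duplication_fraction = stag2_duplication_fraction,
      stag2_exon_deletion_fraction = stag2_exon_deletion_fraction,
      stag2_expression_loss_fraction = stag2_expression_loss_fraction,
      cdkn2a_deletion_fraction = cdkn2a_deletion_fraction,
      tp53_mutation_fraction = tp53_mutation_fraction,
      brca2_k3326x_fraction = brca2_k3326x_fraction,
      fusion_negative_fraction = fusion_negative_fraction,
      nmd_factor = nmd_factor,
      contamination_fraction = contamination_fraction,
      mean_target_coverage = mean_target_coverage,
      library_size = as.integer(library_size),
      true_score_mean = true_score_mean,
      artifact_score_mean = artifact_score_mean,
      score_sd = score_sd,
      artifact_mean_per_sample = 4,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic EFT cohort configuration\n")
  cat(sprintf("  %d tumors + %d cell lines; %d-sample normal panel; seed %d\n",
              x$n_tumors, x$n_cell_lines, x$n_normal_panel, x$seed))
  cat(sprintf("  coding burden Poisson(%.3g) over %.3g bp (%.3g/Mb)\n",
              x$mean_coding_mutations, x$coding_target_bp,
              mutation_rate(x$mean_coding_mutations, x$coding_target_bp)))
  invisible(x)
}
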