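#' Filter structural-variant junctions
#'
#' Removes discordant-mate-pair junction calls that are weakly supported or
#' artifact-prone: footprint smaller than `min_footprint` bases, fewer than
#' `min_mate_pairs` discordant mate pairs, located in an under-represented
#' repeat, or present in the baseline (panel-of-normals) junction set.
#' Surviving rows pass through unchanged.
#'
#' @param junctions A data frame with columns `footprint_bp`,
#'   `discordant_mate_pairs`, `in_repeat`, `in_baseline`.
#' @param min_footprint Minimum junction footprint in bases (default 70).
#' @param min_mate_pairs Minimum discordant mate pairs (default 10).
#' @return Filtered tibble.
#' @export
filter_junctions <- function(junctions, min_footprint = 70,
                             min_mate_pairs = 10) {
  check_columns(junctions,
                c("footprint_bp", "discordant_mate_pairs",
                  "in_repeat", "in_baseline"),
                "junctions")
  if (min_footprint <= 0 || min_mate_pairs <= 0) {
    abort("filter thresholds must be positive")
  }
  drop <- junctions$footprint_bp < min_footprint |
    junctions$discordant_mate_pairs < min_mate_pairs |
    junctions$in_repeat |
    junctions$in_baseline
  as_tibble(junctions[!drop, , drop = FALSE])
}

#' Classify copy-number segment confidence
#'
#' A segment is high-confidence if it is large enough for reliable lesser-
#' allele-fraction estimation (>= 10 kb and >= 10 heterozygous SNPs), or
#' highly altered (homozygous deletion, i.e. copy number 0, or a focal
#' amplification at >= 5 copies), or supported by at least one somatic
#' junction. All other segments are low-confidence.
#'
#' @param segments A data frame with columns `start`, `end` (0-based
#'   half-open), `copy_number`, `het_snp_count`, `junction_supported`.
#' @param min_length Minimum length for the "large" rule (default 10000 bp).
#' @param min_het_snps Minimum heterozygous SNP count (default 10).
#' @param amp_copies Focal-amplification copy threshold (default 5).
#' @return The input as a tibble with an added `confidence` column
#'   (`"high"` / `"low"`).
#' @export
classify_segment_confidence <- function(segments, min_length = 10000,
                                        min_het_snps = 10, amp_copies = 5) {
  check_columns(segments,
                c("start", "end", "copy_number", "het_snp_count",
                  "junction_supported"),
                "segments")
  if (any(segments$end <= segments$start)) {
    abort("segments must satisfy end > start (0-based half-open)")
  }
  high <- ((segments$end - segments$start) >= min_length &
             segments$het_snp_count >= min_het_snps) |
    segments$copy_number == 0 |
    segments$copy_number >= amp_copies |
    segments$junction_supported
  dplyr::mutate(as_tibble(segments),
                confidence = ifelse(high, "high", "low"))
}

#' Per-exon coverage ratios
#'
#' Normalises per-exon mean sequencing depth by the sample's overall mean
#' depth, so that a diploid exon sits near ratio 1 regardless of how deeply
#' the sample was sequenced.
#'
#' @param coverage A data frame with columns `sample_id`, `gene`, `exon`,
#'   `depth`; an optional `sample_mean_depth` column is used as the
#'   denominator, otherwise the per-sample mean of `depth` is used.
#' @return The input as a tibble with `sample_mean_depth` and `ratio`
#'   columns added.
#' @export
exon_coverage_ratio <- function(coverage) {
  check_columns(coverage, c("sample_id", "gene", "exon", "depth"), "coverage")
  if (any(coverage$depth < 0)) abort("depths must be non-negative")
  out <- as_tibble(coverage)
  if (!"sample_mean_depth" %in% names(out)) {
    out <- out |>
      group_by(.data$sample_id) |>
      mutate(sample_mean_depth = mean(.data$depth)) |>
      ungroup()
  }
  if (any(out$sample_mean_depth <= 0)) {
    abort("sample mean depth must be positive for every sample")
  }
  mutate(out, ratio = .data$depth / .data$sample_mean_depth)
}

#' Call copy-number state from exon coverage ratios
#'
#' Scans per-exon normalised coverage ratios gene by gene and assigns one
#' call per sample per gene:
#'
#' * `homozygous_deletion` if the gene-median ratio falls below `t_hom`;
#' * `intragenic_duplication` if a run of at least `min_run` contiguous
#'   exons has ratio >= `t_dup`;
#' * `hemizygous_deletion` if a run of at least `min_run` contiguous exons
#'   has ratio in `[t_hom, t_hemi)`;
#' * `normal` otherwise.
#'
#' Precedence when several rules fire: homozygous deletion, then
#' duplication, then hemizygous deletion. When `normalize = TRUE`, ratios
#' are first divided by the per-exon cohort median to absorb systematic
#' amplicon-efficiency differences between exons.
#'
#' @param ratios A data frame with columns `sample_id`, `gene`, `exon`,
#'   `ratio` (see [exon_coverage_ratio()]).
#' @param genes Optional subset of genes to call (default all).
#' @param t_hom,t_hemi,t_dup Ratio thresholds, required to satisfy
#'   `t_hom < t_hemi < 1 < t_dup`; defaults 0.2 / 0.7 / 1.5.
#' @param min_run Minimum contiguous run length (default 2 exons).
#' @param normalize Divide by the per-exon cohort median first?
#' @return A tibble with one row per sample x gene: `call`, affected
#'   `exon_start` / `exon_end` (NA for `normal`), and the gene-median
#'   ratio.
#' @export
call_coverage_cnv <- function(ratios, genes = NULL, t_hom = 0.2,
                              t_hemi = 0.7, t_dup = 1.5, min_run = 2,
                              normalize = TRUE) {
  check_columns(ratios, c("sample_id", "gene", "exon", "ratio"), "ratios")
  if (!(t_hom < t_hemi && t_hemi < 1 && 1 < t_dup)) {
    abort("thresholds must satisfy t_hom < t_hemi < 1 < t_dup")
  }
  x <- as_tibble(ratios)
  if (!is.null(genes)) x <- filter(x, .data$gene %in% genes)
  if (nrow(x) == 0L) abort("no exons to call")
  if (normalize) {
    x <- x |>
      group_by(.data$gene, .data$exon) |>
      mutate(.exon_median = median(.data$ratio)) |>
      ungroup() |>
      mutate(ratio = ifelse(.data$.exon_median > 0,
                            .data$ratio / .data$.exon_median, .data$ratio)) |>
      select(-".exon_median")
  }

  x |>
    arrange(.data$sample_id, .data$gene, .data$exon) |>
    group_by(.data$sample_id, .data$gene) |>
    dplyr::group_modify(function(d, key) {
      r <- d$ratio
      med <- median(r)
      call <- "normal"; lo <- NA_integer_; hi <- NA_integer_
      dup_runs <- find_runs(r >= t_dup)
      dup_runs <- dup_runs[dup_runs$length >= min_run, ]
      hemi_runs <- find_runs(r >= t_hom & r < t_hemi)
      hemi_runs <- hemi_runs[hemi_runs$length >= min_run, ]
      if (med < t_hom) {
        call <- "homozygous_deletion"
        lo <- d$exon[1L]; hi <- d$exon[nrow(d)]
      } else if (nrow(dup_runs)) {
        best <- dup_runs[which.max(dup_runs$length), ]
        call <- "intragenic_duplication"
        lo <- d$exon[best$start]; hi <- d$exon[best$end]
      } else if (nrow(hemi_runs)) {
        best <- hemi_runs[which.max(hemi_runs$length), ]
        call <- "hemizygous_deletion"
        lo <- d$exon[best$start]; hi <- d$exon[best$end]
      }
      tibble(call = call, exon_start = lo, exon_end = hi, median_ratio = med)
    }) |>
    ungroup()
}
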