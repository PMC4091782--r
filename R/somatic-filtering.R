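#' Protein-altering consequence classes
#'
#' The controlled vocabulary of variant consequences considered protein
#' altering for the rare-variant filter.
#'
#' @export
PROTEIN_ALTERING <- c("missense", "nonsense", "frameshift",
                      "inframe_indel", "splice_site")

#' All recognised consequence classes
#' @export
CONSEQUENCE_LEVELS <- c(PROTEIN_ALTERING, "synonymous", "UTR5", "UTR3",
                        "intronic", "intergenic")

# Trim shared flanking bases from a ref/alt pair so that the same indel is
# keyed identically regardless of padding; positions advance with a trimmed
# prefix. Alleles are assumed already left-aligned against the reference.
trim_allele <- function(pos, ref, alt) {
  # trim common suffix first (keep at least one base on each side)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # then common prefix, advancing pos
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalised variant keys
#'
#' Builds a `chrom:pos:ref:alt` key per variant after trimming shared
#' flanking bases from the allele pair, so that equivalent indel
#' representations compare equal (alleles are assumed left-aligned).
#'
#' @param variants A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A character vector of keys, one per row.
#' @export
variant_keys <- function(variants) {
  check_columns(variants, c("chrom", "pos", "ref", "alt"), "variants")
  if (nrow(variants) == 0L) return(character())
  trimmed <- purrr::pmap(
    list(variants$pos, variants$ref, variants$alt),
    function(pos, ref, alt) trim_allele(pos, ref, alt)
  )
  paste(variants$chrom,
        vapply(trimmed, `[[`, numeric(1), "pos"),
        vapply(trimmed, `[[`, character(1), "ref"),
        vapply(trimmed, `[[`, character(1), "alt"),
        sep = ":")
}

#' Remove variants present in a panel of normals
#'
#' Platform-specific artifacts recur across unrelated normal samples; any
#' putative somatic call whose normalised `(chrom, pos, ref, alt)` key is
#' present in the panel is removed. Input order is preserved.
#'
#' @param variants A data frame of variant calls with columns `chrom`,
#'   `pos`, `ref`, `alt` (additional columns pass through).
#' @param pon A data frame of panel-of-normals sites with the same four
#'   columns, or a character vector of keys as produced by [variant_keys()].
#' @return The rows of `variants` not matching the panel, as a tibble.
#' @export
remove_panel_of_normals <- function(variants, pon) {
  keys <- variant_keys(variants)
  pon_keys <- if (is.character(pon)) pon else variant_keys(pon)
  as_tibble(variants[!(keys %in% pon_keys), , drop = FALSE])
}

is_verified_true <- function(verified) {
  if (is.logical(verified)) !is.na(verified) & verified
  else !is.na(verified) & verified %in% c("true", "TRUE", "True")
}

#' Filter variants by somatic score
#'
#' Keeps variants whose platform somatic score is at or above the cutoff,
#' plus all orthogonally verified variants regardless of score. Order is
#' preserved.
#'
#' @param variants A data frame with columns `somatic_score` and
#'   (optionally) `verified` (logical, or character with `"true"` /
#'   `"false"` / `"untested"`).
#' @param cutoff Finite score cutoff; the default operating point is 3.
#' @return Filtered tibble.
#' @export
filter_by_somatic_score <- function(variants, cutoff = 3) {
  check_columns(variants, "somatic_score", "variants")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff)) {
    abort("`cutoff` must be a single finite score")
  }
  verified <- if ("verified" %in% names(variants)) {
    is_verified_true(variants$verified)
  } else {
    rep(FALSE, nrow(variants))
  }
  keep <- (!is.na(variants$somatic_score) &
             variants$somatic_score >= cutoff) | verified
  as_tibble(variants[keep, , drop = FALSE])
}

#' Calibrate a somatic-score cutoff against verified labels
#'
#' Given variants with binary truth labels (e.g. from orthogonal Sanger
#' verification of high-confidence calls), computes sensitivity and
#' specificity at each candidate cutoff, where predicted-positive means
#' `somatic_score >= cutoff`. The chosen cutoff is the smallest candidate at
#' which both sensitivity and specificity meet the configured minima; if no
#' candidate does (or no minima are given), the smallest candidate
#' maximising Youden's J (sensitivity + specificity - 1) is chosen.
#'
#' @param labeled A data frame with columns `somatic_score` and `truth`
#'   (logical: `TRUE` for verified somatic, `FALSE` for artifact).
#' @param cutoffs Candidate cutoffs; defaults to the sorted unique scores.
#' @param min_sensitivity,min_specificity Optional minima for the operating
#'   point.
#' @return An object of class `eft_calibration`: a list with `table` (one
#'   row per cutoff with confusion counts, sensitivity, specificity,
#'   Youden's J) and `chosen_cutoff`.
#' @export
calibrate_cutoff <- function(labeled, cutoffs = NULL,
                             min_sensitivity = NULL, min_specificity = NULL) {
  check_columns(labeled, c("somatic_score", "truth"), "labeled")
  truth <- as.logical(labeled$truth)
  if (anyNA(truth)) abort("`truth` must be logical with no missing values")
  n_true <- sum(truth)
  n_false <- sum(!truth)
  if (n_true == 0L || n_false == 0L) {
    abort("calibration needs at least one true and one false label; ",
          "sensitivity or specificity is undefined otherwise")
  }
  score <- labeled$somatic_score
  if (is.null(cutoffs)) cutoffs <- sort(unique(score))
  cutoffs <- sort(unique(cutoffs))

  tab <- purrr::map_dfr(cutoffs, function(c) {
    pred <- score >= c
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    tibble(cutoff = c, tp = tp, fp = fp, tn = tn, fn = fn,
           sensitivity = tp / (tp + fn),
           specificity = tn / (tn + fp))
  })
  tab$youden_j <- tab$sensitivity + tab$specificity - 1

  chosen <- NA_real_
  if (!is.null(min_sensitivity) && !is.null(min_specificity)) {
    ok <- tab$sensitivity >= min_sensitivity & tab$specificity >= min_specificity
    if (any(ok)) chosen <- min(tab$cutoff[ok])
  }
  if (is.na(chosen)) {
    best <- tab$youden_j >= max(tab$youden_j) - 1e-12
    chosen <- min(tab$cutoff[best])
  }

  structure(
    list(table = tab, chosen_cutoff = chosen,
         n_true = n_true, n_false = n_false),
    class = "eft_calibration"
  )
}

#' @export
print.eft_calibration <- function(x, ...) {
  cat("Somatic-score cutoff calibration\n")
  cat(sprintf("  labels: %d true, %d false; %d candidate cutoffs\n",
              x$n_true, x$n_false, nrow(x$table)))
  at <- x$table[x$table$cutoff == x$chosen_cutoff, ]
  cat(sprintf("  chosen cutoff %.3g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$chosen_cutoff, 100 * at$sensitivity, 100 * at$specificity))
  invisible(x)
}

#' Keep rare protein-altering variants
#'
#' Retains variants whose consequence is protein altering (missense,
#' nonsense, frameshift, in-frame indel, or splice site) and whose
#' population allele frequency is either unknown (unreported) or below the
#' threshold.
#'
#' @param variants A data frame with columns `consequence` and
#'   `population_af` (`NA` meaning unreported).
#' @param af_threshold Allele-frequency threshold in (0, 1]; default 0.005.
#' @return Filtered tibble, order preserved.
#' @export
rare_coding_filter <- function(variants, af_threshold = 0.005) {
  check_columns(variants, c("consequence", "population_af"), "variants")
  if (!is.numeric(af_threshold) || length(af_threshold) != 1L ||
      is.na(af_threshold) || af_threshold <= 0 || af_threshold > 1) {
    abort("`af_threshold` must be a single value in (0, 1]")
  }
  keep <- variants$consequence %in% PROTEIN_ALTERING &
    (is.na(variants$population_af) | variants$population_af < af_threshold)
  as_tibble(variants[keep, , drop = FALSE])
}

#' Somatic mutation rate per megabase
#'
#' @param variant_count Number of somatic mutations observed.
#' @param target_bp Size of the interrogated target space in base pairs.
#' @return Mutations per Mb: `variant_count * 1e6 / target_bp`.
#' @examples
#' mutation_rate(6, 4e7)  # 0.15, a typical Ewing sarcoma coding rate
#' @export
mutation_rate <- function(variant_count, target_bp) {
  if (any(!is.finite(target_bp)) || any(target_bp <= 0)) {
    abort("`target_bp` must be positive")
  }
  if (any(variant_count < 0)) abort("`variant_count` must be non-negative")
  variant_count * 1e6 / target_bp
}
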