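#' RNA variant allele frequency
#'
#' Computes `VAF = alt / (ref + alt)` from RNA-seq allele counts at each
#' variant position. Reads supporting a third allele are excluded from the
#' denominator; positions with no informative (ref or alt) reads get a
#' missing VAF.
#'
#' @param counts A data frame with columns `ref_reads` and `alt_reads`
#'   (an `other_reads` column, if present, is ignored by the calculation).
#' @return Input as a tibble with a `vaf` column added.
#' @export
variant_allele_frequency <- function(counts) {
  check_columns(counts, c("ref_reads", "alt_reads"), "counts")
  if (any(counts$ref_reads < 0 | counts$alt_reads < 0)) {
    abort("allele counts must be non-negative")
  }
  informative <- counts$ref_reads + counts$alt_reads
  mutate(as_tibble(counts),
         vaf = ifelse(informative > 0,
                      .data$alt_reads / informative, NA_real_))
}

#' Classify allele-specific expression from RNA VAF
#'
#' Partitions the VAF range into qualitative allele-expression classes:
#' `exclusive_mutant` (vaf >= 0.95, e.g. the wild-type-bearing X silenced),
#' `preferential_mutant` (0.60 <= vaf < 0.95, mutant allele dominant with
#' some wild-type signal from admixed normal tissue), `balanced`
#' (0.40 <= vaf < 0.60), and `reference_skewed` (vaf < 0.40). Every VAF in
#' \[0, 1\] receives exactly one label; `NA` propagates.
#'
#' @param vaf Numeric vector of VAFs in \[0, 1\].
#' @param exclusive_threshold,preferential_threshold,balanced_threshold
#'   Partition boundaries (defaults 0.95 / 0.60 / 0.40).
#' @return Character vector of class labels.
#' @export
classify_allelic_expression <- function(vaf, exclusive_threshold = 0.95,
                                        preferential_threshold = 0.60,
                                        balanced_threshold = 0.40) {
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) abort("`vaf` must lie in [0, 1]")
  dplyr::case_when(
    is.na(vaf) ~ NA_character_,
    vaf >= exclusive_threshold ~ "exclusive_mutant",
    vaf >= preferential_threshold ~ "preferential_mutant",
    vaf >= balanced_threshold ~ "balanced",
    TRUE ~ "reference_skewed"
  )
}

#' Build an internally consistent transcript model
#'
#' Exon start phases follow the coding-sequence recursion
#' `phase[i + 1] = (phase[i] + cds[i]) mod 3`, starting in phase 0.
#'
#' @param gene Gene symbol.
#' @param exon_lengths Exon lengths in bases.
#' @param cds_lengths Coding bases per exon (0 for untranslated exons);
#'   must not exceed the exon length.
#' @param strand `"+"` or `"-"` (annotation only).
#' @return Tibble with `gene`, `exon`, `length`, `cds_length`, `phase`.
#' @export
transcript_model <- function(gene, exon_lengths, cds_lengths, strand = "+") {
  if (length(exon_lengths) != length(cds_lengths)) {
    abort("`exon_lengths` and `cds_lengths` must have equal length")
  }
  if (any(cds_lengths > exon_lengths) || any(cds_lengths < 0)) {
    abort("coding length must lie in [0, exon length] for every exon")
  }
  phase <- c(0L, cumsum(cds_lengths) %% 3L)[seq_along(cds_lengths)]
  tibble(gene = gene, strand = strand,
         exon = seq_along(exon_lengths),
         length = as.integer(exon_lengths),
         cds_length = as.integer(cds_lengths),
         phase = as.integer(phase))
}

#' Reading frame of a gene fusion at exon resolution
#'
#' A fusion joining the 5' gene after `exon5` to the 3' gene at `exon3` is
#' in frame when the cumulative coding length of the donor through `exon5`,
#' taken mod 3, equals the start phase of the acceptor exon. If the donor
#' contributes no coding sequence through the junction, or the acceptor
#' exon is untranslated, the chimeric junction is non-coding.
#'
#' @param models Transcript-model tibble covering both genes (see
#'   [transcript_model()] / [transcript_models()]).
#' @param gene5,exon5 Donor (5') gene and its last retained exon.
#' @param gene3,exon3 Acceptor (3') gene and its first retained exon.
#' @return One of `"in_frame"`, `"out_of_frame"`, `"noncoding"`.
#' @export
fusion_frame <- function(models, gene5, exon5, gene3, exon3) {
  check_columns(models, c("gene", "exon", "cds_length", "phase"), "models")
  m5 <- filter(as_tibble(models), .data$gene == gene5)
  m3 <- filter(as_tibble(models), .data$gene == gene3)
  if (!nrow(m5)) abort(sprintf("no transcript model for gene %s", gene5))
  if (!nrow(m3)) abort(sprintf("no transcript model for gene %s", gene3))
  if (!exon5 %in% m5$exon) {
    abort(sprintf("exon %s is not a valid exon of %s", exon5, gene5))
  }
  if (!exon3 %in% m3$exon) {
    abort(sprintf("exon %s is not a valid exon of %s", exon3, gene3))
  }
  donor_cds <- sum(m5$cds_length[m5$exon <= exon5])
  acceptor <- m3[m3$exon == exon3, ]
  if (donor_cds == 0L || acceptor$cds_length == 0L) return("noncoding")
  if (donor_cds %% 3L == acceptor$phase %% 3L) "in_frame" else "out_of_frame"
}

#' Annotate fusion calls with reading-frame status
#'
#' @param fusions Tibble of fusion calls with columns `gene5`, `exon5`,
#'   `gene3`, `exon3`.
#' @param models Transcript-model tibble covering the genes involved;
#'   calls whose genes lack a model get `NA` frame.
#' @return `fusions` with a `frame` column added.
#' @export
annotate_fusion_frame <- function(fusions, models) {
  check_columns(fusions, c("gene5", "exon5", "gene3", "exon3"), "fusions")
  modeled <- unique(models$gene)
  frame <- purrr::pmap_chr(
    fusions[, c("gene5", "exon5", "gene3", "exon3")],
    function(gene5, exon5, gene3, exon3) {
      if (!(gene5 %in% modeled) || !(gene3 %in% modeled)) return(NA_character_)
      fusion_frame(models, gene5, exon5, gene3, exon3)
    }
  )
  mutate(as_tibble(fusions), frame = frame)
}

#' TET-family and ETS-family gene symbols
#' @name fusion_families
#' @export
TET_GENES <- c("EWSR1", "FUS", "TAF15")

#' @rdname fusion_families
#' @export
ETS_GENES <- c("FLI1", "ERG", "FEV", "ETV1", "ETV4")

#' Label fusion calls with their subtype
#'
#' Looks each `(gene5, exon5, gene3, exon3)` junction up in a subtype table
#' (an editable configuration, since type I/II composition is a naming
#' convention rather than biology). Unmatched junctions between a TET
#' family 5' gene and an ETS family 3' gene are labelled
#' `"other variant"`; unmatched junctions of any other gene pair are
#' `"non-TET-ETS"` — the trigger for fusion-negative handling downstream.
#'
#' @param fusions Tibble with `gene5`, `exon5`, `gene3`, `exon3`.
#' @param subtype_table Tibble with those four columns plus `subtype`;
#'   defaults to the shipped table ([fusion_subtype_table()]).
#' @return `fusions` with a `subtype` column added.
#' @export
classify_fusion_subtype <- function(fusions, subtype_table = fusion_subtype_table()) {
  check_columns(fusions, c("gene5", "exon5", "gene3", "exon3"), "fusions")
  check_columns(subtype_table,
                c("gene5", "exon5", "gene3", "exon3", "subtype"),
                "subtype_table")
  out <- as_tibble(fusions) |>
    left_join(select(as_tibble(subtype_table), "gene5", "exon5", "gene3",
                     "exon3", "subtype"),
              by = c("gene5", "exon5", "gene3", "exon3"))
  mutate(out, subtype = dplyr::case_when(
    !is.na(.data$subtype) ~ .data$subtype,
    .data$gene5 %in% TET_GENES & .data$gene3 %in% ETS_GENES ~ "other variant",
    TRUE ~ "non-TET-ETS"
  ))
}

#' Shipped fusion-subtype lookup table
#'
#' Reads the editable junction-to-subtype configuration shipped with the
#' package (EWSR1-FLI1 type I/II and the common variant TET-ETS
#' junctions).
#'
#' @return Tibble with `gene5`, `exon5`, `gene3`, `exon3`, `subtype`.
#' @export
fusion_subtype_table <- function() {
  path <- system.file("extdata", "fusion_subtypes.tsv",
                      package = "eftlandscape", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene5 = "c", exon5 = "i", gene3 = "c", exon3 = "i",
                    subtype = "c"))
}
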