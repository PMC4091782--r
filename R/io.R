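vcf_header <- function() {
  c("##fileformat=VCFv4.2",
    "##source=eftlandscape",
    '##INFO=<ID=SOMSC,Number=1,Type=Float,Description="Somatic score">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=PAF,Number=1,Type=Float,Description="Population allele frequency">',
    '##INFO=<ID=VERIFIED,Number=1,Type=String,Description="Verification status: true/false/untested">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Write somatic variant calls to a VCF v4.2 file
#'
#' Serialises one sample's variant calls, with somatic score, consequence,
#' gene, population allele frequency and verification status carried in
#' the INFO fields (SOMSC, CSQ, GENE, PAF, VERIFIED). The header carries
#' no date line, so identical calls produce byte-identical files.
#'
#' @param variants Tibble of calls for a single sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  check_columns(variants, c("chrom", "pos", "ref", "alt", "somatic_score",
                            "consequence"), "variants")
  gene <- if ("gene" %in% names(variants)) variants$gene else NA_character_
  paf <- if ("population_af" %in% names(variants)) variants$population_af else NA_real_
  verified <- if ("verified" %in% names(variants)) variants$verified else "untested"
  info <- sprintf(
    "SOMSC=%.4f;CSQ=%s%s%s;VERIFIED=%s",
    variants$somatic_score, variants$consequence,
    ifelse(is.na(gene), "", paste0(";GENE=", gene)),
    ifelse(is.na(paf), "", sprintf(";PAF=%.6f", paf)),
    verified)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, as.integer(variants$pos),
                  variants$ref, variants$alt, info)
  writeLines(c(vcf_header(), body), path)
  invisible(path)
}

parse_info_field <- function(info, key, as_numeric = FALSE) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2L]
  if (as_numeric) as.numeric(m) else m
}

#' Read somatic variant calls from a VCF file
#'
#' Parses a VCF written by [write_variant_vcf()] (or any VCF carrying the
#' same INFO fields) back into the package's variant tibble. Requires the
#' `vcfR` package.
#'
#' @param path VCF file path.
#' @param sample_id Sample id to attach to the rows.
#' @return Variant tibble.
#' @export
read_variant_vcf <- function(path, sample_id = NA_character_) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  tibble(
    sample_id = sample_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    somatic_score = parse_info_field(fix$INFO, "SOMSC", as_numeric = TRUE),
    consequence = parse_info_field(fix$INFO, "CSQ"),
    gene = parse_info_field(fix$INFO, "GENE"),
    population_af = parse_info_field(fix$INFO, "PAF", as_numeric = TRUE),
    verified = parse_info_field(fix$INFO, "VERIFIED")
  )
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes every data stream of an [simulate_cohort()] result as plain-text
#' files under `dir`: one VCF per sample in `variants/`, TSVs for the
#' junction, segment, coverage, count, expression, allele-count and fusion
#' tables, the sample sheet, the panel-of-normals site list, and the truth
#' labels as JSON. Output is byte-deterministic for a given cohort.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eft_cohort"))
  dir.create(file.path(dir, "variants"), recursive = TRUE,
             showWarnings = FALSE)
  for (sid in cohort$sample_sheet$sample_id) {
    write_variant_vcf(
      filter(cohort$variants, .data$sample_id == sid),
      file.path(dir, "variants", paste0(sid, ".vcf")))
  }
  tables <- c("sample_sheet", "pon", "junctions", "segments", "coverage",
              "exon_counts", "panel_exon_counts", "gene_fpkm",
              "panel_gene_fpkm", "allele_counts", "fusions")
  for (nm in tables) {
    readr::write_tsv(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(
    lapply(cohort$truth, function(x) if (is.data.frame(x)) x else x),
    file.path(dir, "truth.json"),
    dataframe = "rows", na = "null", digits = NA, pretty = FALSE)
  invisible(dir)
}
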