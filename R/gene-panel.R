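#' Toy targeted gene panel
#'
#' A small, fixed panel of recurrently altered EFT genes with invented but
#' internally consistent exon structures, used by the synthetic cohort
#' generator and its downstream callers. STAG2 carries 33 coding exons (as
#' in the real gene), TP53 11, CDKN2A 4 and BRCA2 12; coordinates are toy
#' positions on the genes' real chromosomes.
#'
#' @return Tibble with `gene`, `chrom`, `exon`, `start`, `end` (0-based
#'   half-open) and `exon_length`.
#' @export
eft_gene_panel <- function() {
  spec <- list(
    STAG2  = list(chrom = "chrX",  n = 33L, base = 1.23e8),
    TP53   = list(chrom = "chr17", n = 11L, base = 7.57e6),
    CDKN2A = list(chrom = "chr9",  n = 4L,  base = 2.19e7),
    BRCA2  = list(chrom = "chr13", n = 12L, base = 3.23e7)
  )
  purrr::imap_dfr(spec, function(s, gene) {
    i <- seq_len(s$n)
    # deterministic, varied exon lengths in ~[90, 230) bp
    len <- 90L + ((i * 37L + nchar(gene) * 11L) %% 140L)
    start <- s$base + cumsum(c(0L, head(len, -1L) + 1800L))
    tibble(gene = gene, chrom = s$chrom, exon = i,
           start = as.integer(start), end = as.integer(start + len),
           exon_length = len)
  })
}

#' Synthetic Ewing sarcoma signature gene set
#'
#' Stand-in list of genes treated as up-regulated in TET-ETS
#' fusion-positive samples by the synthetic cohort generator: canonical
#' EWSR1-FLI1 targets and Ewing-signature members. Published signature
#' lists live in prior work and are replaced here by this configurable
#' stand-in; the block is deliberately wide (24 genes) because the
#' fusion-driven expression profile spans a large gene set and must
#' dominate the expression variance for clustering to isolate
#' fusion-negative samples, as it does in real cohorts.
#'
#' @return Character vector of gene symbols.
#' @export
eft_signature_genes <- function() {
  c("NR0B1", "NKX2-2", "GLI1", "CAV1", "CAV2", "CCND1", "EZH2", "PTPN13",
    "DKK2", "PAPPA", "PRKCB", "CACNB2", "STEAP1", "IGF1", "PTCH1", "ID2",
    "MYC", "TNC", "VEGFA", "CD99", "SOX2", "ATP1A1", "FCGRT", "LIPI")
}

#' Transcript models for the fusion genes
#'
#' Invented but phase-consistent single-transcript models for the TET/ETS
#' fusion partners and the alternate fusion genes, built with
#' [transcript_model()] so that the canonical junctions (EWSR1 exon 7 to
#' FLI1 exon 6 or 5, FUS exon 6 to NFATc2 exon 9, CIC exon 20 to FOXO4
#' exon 2, ETV6 exon 5 to NTRK3 exon 13) are reading-frame compatible.
#'
#' @return Tibble of transcript models (one designated transcript per
#'   gene).
#' @export
transcript_models <- function() {
  bind_rows(
    transcript_model("EWSR1",
      exon_lengths = c(300, 100, 110, 120, 90, 130, 152, 97, 101, 650),
      cds_lengths  = c(63, 100, 110, 120, 90, 130, 152, 97, 101, 150)),
    transcript_model("FLI1",
      exon_lengths = c(400, 120, 111, 102, 117, 160, 95, 130, 1500),
      cds_lengths  = c(0, 120, 111, 102, 117, 160, 95, 130, 200)),
    transcript_model("ERG",
      exon_lengths = c(350, 45, 120, 99, 120, 218, 100, 900),
      cds_lengths  = c(0, 45, 120, 99, 120, 218, 100, 160)),
    transcript_model("FEV",
      exon_lengths = c(360, 130, 950),
      cds_lengths  = c(240, 130, 331)),
    transcript_model("FUS",
      exon_lengths = c(180, 93, 120, 90, 105, 108, 140, 800),
      cds_lengths  = c(60, 93, 120, 90, 105, 108, 140, 210)),
    transcript_model("NFATc2",
      exon_lengths = c(280, 90, 120, 105, 99, 120, 90, 96, 131, 1100),
      cds_lengths  = c(0, 90, 120, 105, 99, 120, 90, 96, 131, 250)),
    transcript_model("CIC",
      exon_lengths = c(250, rep(105, 18), 120, 1200),
      cds_lengths  = c(0, rep(105, 18), 120, 300)),
    transcript_model("FOXO4",
      exon_lengths = c(500, 130, 140, 900),
      cds_lengths  = c(303, 130, 140, 100)),
    transcript_model("ETV6",
      exon_lengths = c(200, 120, 90, 141, 99, 120, 90, 1100),
      cds_lengths  = c(57, 120, 90, 141, 99, 120, 90, 300)),
    transcript_model("NTRK3",
      exon_lengths = c(300, rep(96, 11), 150, 120, 1200),
      cds_lengths  = c(0, rep(96, 11), 150, 120, 399))
  )
}
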