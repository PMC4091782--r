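BASES <- c("A", "C", "G", "T")

random_snv <- function(n) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

# one EWSR1/alternate fusion label -> junction coordinates on the toy models
fusion_junction <- function(label) {
  switch(label,
    "EWSR1-FLI1 type I"  = list(gene5 = "EWSR1", exon5 = 7L, gene3 = "FLI1", exon3 = 6L),
    "EWSR1-FLI1 type II" = list(gene5 = "EWSR1", exon5 = 7L, gene3 = "FLI1", exon3 = 5L),
    "EWSR1-FLI1 variant 9-6"  = list(gene5 = "EWSR1", exon5 = 9L, gene3 = "FLI1", exon3 = 6L),
    "EWSR1-FLI1 variant 10-6" = list(gene5 = "EWSR1", exon5 = 10L, gene3 = "FLI1", exon3 = 6L),
    "EWSR1-ERG"  = list(gene5 = "EWSR1", exon5 = 7L, gene3 = "ERG", exon3 = 6L),
    "EWSR1-FEV"  = list(gene5 = "EWSR1", exon5 = 7L, gene3 = "FEV", exon3 = 2L),
    "FUS-NFATc2" = list(gene5 = "FUS", exon5 = 6L, gene3 = "NFATc2", exon3 = 9L),
    "CIC-FOXO4"  = list(gene5 = "CIC", exon5 = 20L, gene3 = "FOXO4", exon3 = 2L),
    "ETV6-NTRK3" = list(gene5 = "ETV6", exon5 = 5L, gene3 = "NTRK3", exon3 = 13L),
    NULL
  )
}

FUSION_GENE_CHROM <- c(EWSR1 = "chr22", FLI1 = "chr11", ERG = "chr21",
                       FEV = "chr2", FUS = "chr16", NFATc2 = "chr20",
                       CIC = "chr19", FOXO4 = "chrX", ETV6 = "chr12",
                       NTRK3 = "chr15")

GENE_LEVEL_BASE <- c(STAG2 = 5.3, TP53 = 3.5, CDKN1A = 4.8, CDKN2A = 4.5,
                     BRCA2 = 3.0, EWSR1 = 6.0, FLI1 = 4.0)

EXON_RPKM_BASE <- c(STAG2 = 40, TP53 = 60, CDKN2A = 25, BRCA2 = 10)

#' Simulate a synthetic EFT sequencing cohort
#'
#' Generates, deterministically from the configuration seed, every data
#' stream the downstream analysis stages consume: per-sample somatic
#' variant calls (true calls and panel-of-normals artifacts with
#' partially overlapping score distributions), structural-variant
#' junctions, copy-number segments, per-exon targeted-sequencing coverage,
#' exon-level RNA counts (library sizes conserved exactly), gene-level
#' log2 FPKM for cohort and normal reference panel, RNA allele counts at
#' variant positions, fusion calls, and the complete truth labels the
#' generator planted.
#'
#' Planted biology: STAG2 truncating mutations reduce the gene's exon
#' counts by the nonsense-mediated-decay retention factor (plus the signal
#' from admixed normal tissue); CDKN2A homozygous deletions give near-zero
#' coverage and counts over the deleted exons; STAG2 intragenic
#' duplications double coverage over a contiguous exon run; multi-exon
#' STAG2 deletions null expression of a contiguous run; mutant-allele RNA
#' expression at STAG2 is skewed to the single expressed allele, diluted
#' only by contamination; TET-ETS fusion-positive samples carry an
#' up-regulated expression signature that fusion-negative samples lack.
#'
#' @param config A [cohort_config()].
#' @return An object of class `eft_cohort`: a list of tibbles
#'   (`sample_sheet`, `variants`, `pon`, `junctions`, `segments`,
#'   `coverage`, `exon_counts`, `panel_exon_counts`, `gene_fpkm`,
#'   `panel_gene_fpkm`, `allele_counts`, `fusions`) plus `truth` and the
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config()")
  }
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  panel <- eft_gene_panel()
  n <- config$n_tumors + config$n_cell_lines

  sample_sheet <- tibble(
    sample_id = c(sprintf("EFT-T%03d", seq_len(config$n_tumors)),
                  sprintf("EFT-C%03d", seq_len(config$n_cell_lines))),
    class = c(rep("tumor", config$n_tumors),
              rep("cell_line", config$n_cell_lines))
  ) |>
    mutate(contamination = ifelse(.data$class == "tumor",
                                  config$contamination_fraction, 0))

  ## ---- per-sample truth -------------------------------------------------
  pos_labels <- c("EWSR1-FLI1 type I", "EWSR1-FLI1 type II",
                  "EWSR1-FLI1 variant 9-6", "EWSR1-FLI1 variant 10-6",
                  "EWSR1-ERG", "EWSR1-FEV")
  pos_probs <- c(0.51, 0.20, 0.10, 0.10, 0.05, 0.04)
  neg_labels <- c("none", "FUS-NFATc2", "CIC-FOXO4", "ETV6-NTRK3")
  neg_probs <- c(0.40, 0.20, 0.20, 0.20)

  fusion_negative <- ifelse(sample_sheet$class == "tumor",
                            runif(n) < config$fusion_negative_fraction,
                            FALSE)
  fusion <- character(n)
  for (i in seq_len(n)) {
    fusion[i] <- if (fusion_negative[i]) {
      sample(neg_labels, 1L, prob = neg_probs)
    } else {
      sample(pos_labels, 1L, prob = pos_probs)
    }
  }

  stag2_levels <- c("truncating", "duplication", "exon_deletion",
                    "expression_loss", "intact")
  stag2_probs <- c(config$stag2_truncating_fraction,
                   config$stag2_duplication_fraction,
                   config$stag2_exon_deletion_fraction,
                   config$stag2_expression_loss_fraction)
  stag2_probs <- c(stag2_probs, 1 - sum(stag2_probs))
  stag2_status <- sample(stag2_levels, n, replace = TRUE, prob = stag2_probs)

  n_stag2_exons <- max(panel$exon[panel$gene == "STAG2"])
  run_start <- rep(NA_integer_, n); run_len <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (stag2_status[i] == "duplication") {
      run_len[i] <- sample(3:8, 1L)
      run_start[i] <- sample(2:(n_stag2_exons - run_len[i]), 1L)
    } else if (stag2_status[i] == "exon_deletion") {
      run_len[i] <- sample(4:10, 1L)
      run_start[i] <- sample(2:(n_stag2_exons - run_len[i]), 1L)
    }
  }

  tp53_mut <- runif(n) < config$tp53_mutation_fraction
  tp53_consequence <- ifelse(
    tp53_mut,
    sample(c("missense", "nonsense", "frameshift"), n, replace = TRUE,
           prob = c(0.5, 0.25, 0.25)),
    NA_character_)
  cdkn2a_deleted <- runif(n) < config$cdkn2a_deletion_fraction
  brca2_k3326x <- runif(n) < config$brca2_k3326x_fraction

  truth_samples <- sample_sheet |>
    mutate(fusion = fusion,
           fusion_positive = !fusion_negative,
           stag2_status = stag2_status,
           stag2_run_start = run_start,
           stag2_run_len = run_len,
           tp53_consequence = tp53_consequence,
           cdkn2a_deleted = cdkn2a_deleted,
           brca2_k3326x = brca2_k3326x)

  ## ---- variants and panel-of-normals artifacts --------------------------
  pon_sites <- {
    g <- panel[sample(nrow(panel), 40L, replace = TRUE), ]
    alleles <- random_snv(40L)
    tibble(chrom = g$chrom,
           pos = as.integer(g$start + 1L +
                              floor(runif(40L) * g$exon_length)),
           ref = alleles$ref, alt = alleles$alt)
  }

  variant_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sample_sheet$sample_id[i]
    rows <- list()

    drivers <- 0L
    if (stag2_status[i] == "truncating") {
      csq <- sample(c("nonsense", "frameshift", "splice_site"), 1L,
                    prob = c(0.5, 0.3, 0.2))
      recurrent <- runif(1) < 0.3 && csq == "nonsense"
      ex <- if (recurrent) 8L else sample(seq_len(n_stag2_exons), 1L)
      exrow <- panel[panel$gene == "STAG2" & panel$exon == ex, ]
      pos <- if (recurrent) exrow$start + 61L else
        exrow$start + 1L + floor(runif(1) * exrow$exon_length)
      alle <- random_snv(1L)
      ref <- alle$ref; alt <- alle$alt
      if (csq == "frameshift") { ref <- paste0(ref, "CA"); alt <- substr(ref, 1, 1) }
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid, chrom = "chrX", pos = as.integer(pos),
        ref = ref, alt = alt, gene = "STAG2", consequence = csq,
        population_af = NA_real_, is_somatic = TRUE)
      drivers <- drivers + 1L
    }
    if (tp53_mut[i]) {
      exrow <- panel[panel$gene == "TP53", ]
      exrow <- exrow[sample(nrow(exrow), 1L), ]
      alle <- random_snv(1L)
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid, chrom = exrow$chrom,
        pos = as.integer(exrow$start + 1L +
                           floor(runif(1) * exrow$exon_length)),
        ref = alle$ref, alt = alle$alt, gene = "TP53",
        consequence = tp53_consequence[i],
        population_af = NA_real_, is_somatic = TRUE)
      drivers <- drivers + 1L
    }
    if (brca2_k3326x[i]) {
      exrow <- panel[panel$gene == "BRCA2" & panel$exon == 12L, ]
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid, chrom = exrow$chrom,
        pos = as.integer(exrow$start + 40L),
        ref = "A", alt = "T", gene = "BRCA2", consequence = "nonsense",
        population_af = 0.011, is_somatic = TRUE)
      drivers <- drivers + 1L
    }

    n_total <- rpois(1L, config$mean_coding_mutations)
    n_passenger <- max(0L, n_total - drivers)
    if (n_passenger > 0L) {
      # passengers fall across the whole coding target space; the panel
      # genes are a negligible fraction of it, so they land in invented
      # background genes
      alleles <- random_snv(n_passenger)
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid,
        chrom = sample(paste0("chr", 1:22), n_passenger, replace = TRUE),
        pos = as.integer(floor(runif(n_passenger, 1e6, 2e8))),
        ref = alleles$ref, alt = alleles$alt,
        gene = sprintf("BGENE%03d", sample.int(400L, n_passenger,
                                               replace = TRUE)),
        consequence = sample(
          c("missense", "synonymous", "nonsense", "frameshift",
            "splice_site", "inframe_indel", "UTR3", "intronic"),
          n_passenger, replace = TRUE,
          prob = c(0.45, 0.20, 0.05, 0.05, 0.05, 0.05, 0.08, 0.07)),
        population_af = ifelse(runif(n_passenger) < 0.1,
                               runif(n_passenger) * 0.004, NA_real_),
        is_somatic = TRUE)
    }

    n_art <- min(rpois(1L, config$artifact_mean_per_sample), nrow(pon_sites))
    if (n_art > 0L) {
      art <- pon_sites[sample(nrow(pon_sites), n_art), ]
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid, chrom = art$chrom, pos = art$pos,
        ref = art$ref, alt = art$alt, gene = NA_character_,
        consequence = sample(c("intronic", "intergenic", "missense",
                               "synonymous"),
                             n_art, replace = TRUE,
                             prob = c(0.4, 0.3, 0.2, 0.1)),
        population_af = NA_real_, is_somatic = FALSE)
    }
    variant_rows[[i]] <- bind_rows(rows)
  }
  truth_variants <- bind_rows(variant_rows) |>
    mutate(somatic_score = ifelse(
      .data$is_somatic,
      rnorm(dplyr::n(), config$true_score_mean, config$score_sd),
      rnorm(dplyr::n(), config$artifact_score_mean, config$score_sd)),
      verified = "untested")
  variants <- select(truth_variants, -"is_somatic")

  ## ---- junctions --------------------------------------------------------
  junction_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sample_sheet$sample_id[i]
    rows <- list()
    jx <- fusion_junction(fusion[i])
    if (!is.null(jx)) {
      rows[[1L]] <- tibble(
        sample_id = sid,
        chrom_l = unname(FUSION_GENE_CHROM[jx$gene5]),
        pos_l = 2.96e7 + sample.int(5e4, 1L),
        strand_l = "+",
        chrom_r = unname(FUSION_GENE_CHROM[jx$gene3]),
        pos_r = 1.28e8 + sample.int(5e4, 1L),
        strand_r = "-",
        footprint_bp = 70L + rpois(1L, 60),
        discordant_mate_pairs = 10L + rpois(1L, 25),
        in_repeat = FALSE, in_baseline = FALSE,
        gene = jx$gene5, somatic = TRUE)
    }
    if (stag2_status[i] == "duplication") {
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid, chrom_l = "chrX", pos_l = 1.23e8 + sample.int(3e4, 1L),
        strand_l = "+", chrom_r = "chrX", pos_r = 1.231e8 + sample.int(3e4, 1L),
        strand_r = "-", footprint_bp = 70L + rpois(1L, 50),
        discordant_mate_pairs = 10L + rpois(1L, 15),
        in_repeat = FALSE, in_baseline = FALSE,
        gene = "STAG2", somatic = TRUE)
    }
    n_noise <- rpois(1L, 12)
    if (n_noise > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid,
        chrom_l = sample(paste0("chr", 1:22), n_noise, replace = TRUE),
        pos_l = floor(runif(n_noise, 1e6, 2e8)),
        strand_l = sample(c("+", "-"), n_noise, replace = TRUE),
        chrom_r = sample(paste0("chr", 1:22), n_noise, replace = TRUE),
        pos_r = floor(runif(n_noise, 1e6, 2e8)),
        strand_r = sample(c("+", "-"), n_noise, replace = TRUE),
        footprint_bp = as.integer(floor(runif(n_noise, 20, 160))),
        discordant_mate_pairs = rpois(n_noise, 7),
        in_repeat = runif(n_noise) < 0.25,
        in_baseline = runif(n_noise) < 0.25,
        gene = NA_character_, somatic = FALSE)
    }
    junction_rows[[i]] <- bind_rows(rows)
  }
  junctions <- bind_rows(junction_rows)

  ## ---- copy-number segments ---------------------------------------------
  segment_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sample_sheet$sample_id[i]
    rows <- list()
    n_arm <- sample(2:4, 1L)
    rows[[1L]] <- tibble(
      sample_id = sid,
      chrom = sample(paste0("chr", c(1, 2, 8, 12, 16)), n_arm, replace = TRUE),
      start = floor(runif(n_arm, 1e6, 5e7)),
      end = NA_real_,
      copy_number = sample(c(1, 2, 3), n_arm, replace = TRUE,
                           prob = c(0.25, 0.5, 0.25)),
      het_snp_count = rpois(n_arm, 200),
      junction_supported = FALSE) |>
      mutate(end = .data$start + floor(runif(n_arm, 2e6, 5e7)),
             laf = ifelse(.data$copy_number == 2,
                          pmin(0.5, 0.5 - abs(rnorm(n_arm, 0, 0.02))),
                          pmax(0, 0.33 + rnorm(n_arm, 0, 0.03))))
    if (cdkn2a_deleted[i]) {
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid, chrom = "chr9",
        start = 2.19e7 - 1e4, end = 2.19e7 + 6e4,
        copy_number = 0, het_snp_count = 0L,
        junction_supported = runif(1) < 0.5, laf = 0)
    }
    if (stag2_status[i] == "duplication") {
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid, chrom = "chrX",
        start = 1.23e8, end = 1.23e8 + 4e4,
        copy_number = 4, het_snp_count = rpois(1L, 4),
        junction_supported = TRUE, laf = 0.25)
    }
    n_small <- rpois(1L, 3)
    if (n_small > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = sid,
        chrom = sample(paste0("chr", 1:22), n_small, replace = TRUE),
        start = floor(runif(n_small, 1e6, 2e8)),
        end = NA_real_,
        copy_number = pmax(0.5, 2 + rnorm(n_small, 0, 0.4)),
        het_snp_count = rpois(n_small, 3),
        junction_supported = FALSE) |>
        mutate(end = .data$start + floor(runif(n_small, 1e3, 8e3)),
               laf = pmin(0.5, pmax(0, rnorm(n_small, 0.4, 0.1))))
    }
    segment_rows[[i]] <- bind_rows(rows)
  }
  segments <- bind_rows(segment_rows)

  ## ---- targeted-sequencing exon coverage --------------------------------
  amplicon_eff <- exp(rnorm(nrow(panel), 0, 0.25))
  coverage_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ratio <- rep(1, nrow(panel))
    if (cdkn2a_deleted[i]) ratio[panel$gene == "CDKN2A"] <- 0.05
    if (stag2_status[i] == "duplication") {
      run <- run_start[i]:(run_start[i] + run_len[i] - 1L)
      ratio[panel$gene == "STAG2" & panel$exon %in% run] <- 2
    }
    if (stag2_status[i] == "exon_deletion") {
      run <- run_start[i]:(run_start[i] + run_len[i] - 1L)
      ratio[panel$gene == "STAG2" & panel$exon %in% run] <- 0.5
    }
    sample_factor <- exp(rnorm(1L, 0, 0.1))
    depth <- config$mean_target_coverage * amplicon_eff * sample_factor *
      ratio * exp(rnorm(nrow(panel), 0, 0.08))
    coverage_rows[[i]] <- tibble(
      sample_id = sample_sheet$sample_id[i],
      gene = panel$gene, exon = panel$exon,
      depth = round(depth, 1))
  }
  coverage <- bind_rows(coverage_rows)

  ## ---- RNA exon counts (library sizes conserved exactly) ----------------
  exon_grid <- bind_rows(
    select(panel, "gene", "exon", "exon_length"),
    tibble(gene = "__other__", exon = 1L, exon_length = 5e7)
  )
  base_reads <- ifelse(
    exon_grid$gene == "__other__",
    config$library_size,
    unname(EXON_RPKM_BASE[exon_grid$gene]) * exon_grid$exon_length *
      config$library_size / 1e9
  )

  draw_exon_counts <- function(sid, expected) {
    counts <- rmultinom(1L, config$library_size, prob = expected)[, 1L]
    tibble(gene = exon_grid$gene, exon = exon_grid$exon,
           exon_length = exon_grid$exon_length, sample_id = sid,
           count = as.integer(counts),
           library_size = config$library_size)
  }

  exon_count_rows <- vector("list", n)
  for (i in seq_len(n)) {
    c_frac <- sample_sheet$contamination[i]
    gene_mult <- c(STAG2 = 1, TP53 = 1, CDKN2A = 1, BRCA2 = 1,
                   "__other__" = 1)
    if (stag2_status[i] %in% c("truncating", "expression_loss")) {
      gene_mult["STAG2"] <- c_frac + (1 - c_frac) * config$nmd_factor
    }
    # truncating TP53 transcripts are also subject to nonsense-mediated decay
    if (!is.na(tp53_consequence[i]) && tp53_consequence[i] != "missense") {
      gene_mult["TP53"] <- c_frac + (1 - c_frac) * config$nmd_factor
    }
    if (cdkn2a_deleted[i]) gene_mult["CDKN2A"] <- 0.02
    expected <- base_reads * unname(gene_mult[exon_grid$gene]) *
      exp(rnorm(nrow(exon_grid), 0, 0.10))
    if (stag2_status[i] == "exon_deletion") {
      run <- run_start[i]:(run_start[i] + run_len[i] - 1L)
      expected[exon_grid$gene == "STAG2" & exon_grid$exon %in% run] <-
        expected[exon_grid$gene == "STAG2" & exon_grid$exon %in% run] * 0.05
    }
    if (stag2_status[i] == "duplication") {
      run <- run_start[i]:(run_start[i] + run_len[i] - 1L)
      expected[exon_grid$gene == "STAG2" & exon_grid$exon %in% run] <-
        expected[exon_grid$gene == "STAG2" & exon_grid$exon %in% run] * 1.5
    }
    exon_count_rows[[i]] <- draw_exon_counts(sample_sheet$sample_id[i],
                                             expected)
  }
  exon_counts <- bind_rows(exon_count_rows)

  panel_ids <- sprintf("NORM-%03d", seq_len(config$n_normal_panel))
  panel_exon_counts <- bind_rows(lapply(panel_ids, function(sid) {
    expected <- base_reads * exp(rnorm(nrow(exon_grid), 0, 0.10))
    draw_exon_counts(sid, expected)
  }))

  ## ---- gene-level log2 FPKM ---------------------------------------------
  genes_fpkm <- c(names(GENE_LEVEL_BASE), eft_signature_genes())
  base_fpkm <- c(GENE_LEVEL_BASE,
                 setNames(rep(2, length(eft_signature_genes())),
                          eft_signature_genes()))
  gene_fpkm_rows <- vector("list", n)
  for (i in seq_len(n)) {
    x <- base_fpkm
    c_frac <- sample_sheet$contamination[i]
    if (!fusion_negative[i]) {
      x[eft_signature_genes()] <- x[eft_signature_genes()] + 3
      x["FLI1"] <- x["FLI1"] + 2
    }
    stag2_hit <- stag2_status[i] %in% c("truncating", "expression_loss")
    if (stag2_hit) {
      x["STAG2"] <- x["STAG2"] +
        log2(c_frac + (1 - c_frac) * config$nmd_factor)
      x["TP53"] <- x["TP53"] + 1.8
      x["CDKN1A"] <- x["CDKN1A"] - 2.2
    }
    if (stag2_status[i] == "exon_deletion") x["STAG2"] <- x["STAG2"] - 0.8
    if (!is.na(tp53_consequence[i])) x["CDKN1A"] <- x["CDKN1A"] - 2.5
    if (cdkn2a_deleted[i]) x["CDKN2A"] <- x["CDKN2A"] - 5
    gene_fpkm_rows[[i]] <- tibble(
      gene = genes_fpkm, sample_id = sample_sheet$sample_id[i],
      log2_fpkm = unname(x[genes_fpkm]) + rnorm(length(genes_fpkm), 0, 0.4))
  }
  gene_fpkm <- bind_rows(gene_fpkm_rows)
  panel_gene_fpkm <- bind_rows(lapply(panel_ids, function(sid) {
    tibble(gene = genes_fpkm, sample_id = sid,
           log2_fpkm = unname(base_fpkm[genes_fpkm]) +
             rnorm(length(genes_fpkm), 0, 0.4))
  }))

  ## ---- RNA allele counts at variant positions ---------------------------
  ase_variants <- truth_variants |>
    filter(.data$is_somatic,
           .data$gene %in% c("STAG2", "TP53", "BRCA2"),
           .data$consequence %in% PROTEIN_ALTERING)
  contamination <- setNames(sample_sheet$contamination,
                            sample_sheet$sample_id)
  vaf_true <- ifelse(ase_variants$gene == "STAG2",
                     1 - contamination[ase_variants$sample_id],
                     0.5)
  depth <- rpois(nrow(ase_variants), 120)
  depth[depth == 0L] <- 1L
  alt <- rbinom(nrow(ase_variants), depth, vaf_true)
  allele_counts <- tibble(
    sample_id = ase_variants$sample_id,
    chrom = ase_variants$chrom, pos = ase_variants$pos,
    gene = ase_variants$gene,
    ref_reads = depth - alt, alt_reads = alt,
    other_reads = rpois(nrow(ase_variants), 1),
    vaf_true = unname(vaf_true))

  ## ---- fusion calls ------------------------------------------------------
  fusion_rows <- purrr::map2(sample_sheet$sample_id, fusion, function(sid, f) {
    jx <- fusion_junction(f)
    if (is.null(jx)) return(NULL)
    tibble(sample_id = sid, gene5 = jx$gene5, exon5 = jx$exon5,
           gene3 = jx$gene3, exon3 = jx$exon3,
           spanning_reads = 5L + rpois(1L, 60))
  })
  fusions <- bind_rows(fusion_rows)

  structure(
    list(
      config = config,
      sample_sheet = sample_sheet,
      variants = variants,
      pon = pon_sites,
      junctions = select(junctions, -"gene", -"somatic"),
      segments = segments,
      coverage = coverage,
      exon_counts = exon_counts,
      panel_exon_counts = panel_exon_counts,
      gene_fpkm = gene_fpkm,
      panel_gene_fpkm = panel_gene_fpkm,
      allele_counts = select(allele_counts, -"vaf_true"),
      fusions = fusions,
      truth = list(samples = truth_samples,
                   variants = truth_variants,
                   junctions = junctions,
                   allele_counts = allele_counts)
    ),
    class = "eft_cohort"
  )
}

#' @export
print.eft_cohort <- function(x, ...) {
  cat(sprintf("Synthetic EFT cohort: %d tumors, %d cell lines, %d-sample normal panel (seed %d)\n",
              x$config$n_tumors, x$config$n_cell_lines,
              x$config$n_normal_panel, x$config$seed))
  cat(sprintf("  %d variant calls (%d artifact), %d junctions, %d segments, %d fusion calls\n",
              nrow(x$variants), sum(!x$truth$variants$is_somatic),
              nrow(x$junctions), nrow(x$segments), nrow(x$fusions)))
  invisible(x)
}

#' Truth table of planted gene alterations
#'
#' Flattens the generator's per-sample truth into one row per planted
#' (sample, gene, alteration class), the reference for parameter-recovery
#' checks against the downstream callers.
#'
#' @param cohort An [simulate_cohort()] result.
#' @return Tibble with `sample_id`, `gene`, `alteration`.
#' @export
truth_alterations <- function(cohort) {
  s <- cohort$truth$samples
  bind_rows(
    s |> filter(.data$stag2_status == "truncating") |>
      mutate(gene = "STAG2", alteration = "truncating_mutation"),
    s |> filter(.data$stag2_status == "duplication") |>
      mutate(gene = "STAG2", alteration = "intragenic_duplication"),
    s |> filter(.data$stag2_status == "exon_deletion") |>
      mutate(gene = "STAG2", alteration = "contiguous_exon_loss"),
    s |> filter(.data$stag2_status == "expression_loss") |>
      mutate(gene = "STAG2", alteration = "expression_loss"),
    s |> filter(!is.na(.data$tp53_consequence)) |>
      mutate(gene = "TP53",
             alteration = ifelse(.data$tp53_consequence == "missense",
                                 "point_mutation", "truncating_mutation")),
    s |> filter(.data$cdkn2a_deleted) |>
      mutate(gene = "CDKN2A", alteration = "homozygous_deletion")
  ) |>
    select("sample_id", "gene", "alteration")
}

#' Draw a labelled verification set from a synthetic cohort
#'
#' Emulates orthogonal (Sanger-style) verification: samples `n_true`
#' genuinely somatic calls and `n_artifact` platform artifacts from the
#' cohort's variant calls and returns them with binary truth labels. The
#' score distributions of the two classes overlap partially, so cutoff
#' calibration on the result is informative rather than trivial.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param n_true,n_artifact Requested class sizes (`n_true + n_artifact`
#'   must be at least 2; counts must not exceed the available calls).
#' @param seed Integer seed for the draw.
#' @return Tibble of variants with a logical `truth` column.
#' @export
generate_verification_set <- function(cohort, n_true, n_artifact,
                                      seed = cohort$config$seed + 1L) {
  check_count(n_true, "n_true", positive = FALSE)
  check_count(n_artifact, "n_artifact", positive = FALSE)
  if (n_true + n_artifact < 2L) {
    abort("`n_true + n_artifact` must be at least 2")
  }
  pool_true <- filter(cohort$truth$variants, .data$is_somatic)
  pool_art <- filter(cohort$truth$variants, !.data$is_somatic)
  if (n_true > nrow(pool_true)) {
    abort(sprintf("requested %d true variants but only %d are available",
                  n_true, nrow(pool_true)))
  }
  if (n_artifact > nrow(pool_art)) {
    abort(sprintf("requested %d artifact variants but only %d are available",
                  n_artifact, nrow(pool_art)))
  }
  withr::with_seed(seed, {
    picked <- bind_rows(
      pool_true[sample(nrow(pool_true), n_true), ],
      pool_art[sample(nrow(pool_art), n_artifact), ]
    )
    picked |>
      mutate(truth = .data$is_somatic,
             verified = ifelse(.data$is_somatic, "true", "false")) |>
      select(-"is_somatic")
  })
}
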