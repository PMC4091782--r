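make_junctions <- function(footprint, pairs, repeat_flag = FALSE,
                           baseline = FALSE) {
  tibble::tibble(sample_id = "S1", footprint_bp = footprint,
                 discordant_mate_pairs = pairs,
                 in_repeat = repeat_flag, in_baseline = baseline)
}

make_segments <- function(length_bp, het = 0, cn = 2, supported = FALSE) {
  tibble::tibble(sample_id = "S1", chrom = "chr1", start = 0,
                 end = length_bp, copy_number = cn, het_snp_count = het,
                 laf = 0.4, junction_supported = supported)
}

test_that("junction filter removes small-footprint and weakly supported calls", {
  expect_equal(nrow(filter_junctions(make_junctions(50, 12))), 0L)
  expect_equal(nrow(filter_junctions(make_junctions(100, 9))), 0L)
  expect_equal(nrow(filter_junctions(make_junctions(100, 12))), 1L)
  expect_equal(nrow(filter_junctions(make_junctions(100, 12, repeat_flag = TRUE))), 0L)
  expect_equal(nrow(filter_junctions(make_junctions(100, 12, baseline = TRUE))), 0L)
  # boundary: exactly at thresholds is retained
  expect_equal(nrow(filter_junctions(make_junctions(70, 10))), 1L)
})

test_that("segment confidence covers the three high-confidence routes", {
  expect_equal(classify_segment_confidence(make_segments(12000, het = 15, cn = 1))$confidence, "high")
  expect_equal(classify_segment_confidence(make_segments(2000, cn = 0))$confidence, "high")
  expect_equal(classify_segment_confidence(make_segments(2000, cn = 6))$confidence, "high")
  expect_equal(classify_segment_confidence(make_segments(2000, cn = 3, supported = TRUE))$confidence, "high")
  expect_equal(classify_segment_confidence(make_segments(5000, het = 3, cn = 3))$confidence, "low")
  # large but SNP-poor is not enough
  expect_equal(classify_segment_confidence(make_segments(50000, het = 5, cn = 3))$confidence, "low")
})

test_that("junction and segment rules equal direct boolean oracles on random records", {
  set.seed(33)
  n <- 2000
  j <- tibble::tibble(
    sample_id = "S", footprint_bp = sample.int(200, n, TRUE),
    discordant_mate_pairs = sample.int(30, n, TRUE) - 1L,
    in_repeat = runif(n) < 0.2, in_baseline = runif(n) < 0.2)
  keep_oracle <- !(j$footprint_bp < 70 | j$discordant_mate_pairs < 10 |
                     j$in_repeat | j$in_baseline)
  expect_equal(filter_junctions(j), tibble::as_tibble(j[keep_oracle, ]))

  s <- tibble::tibble(
    sample_id = "S", chrom = "chr1", start = 0,
    end = sample.int(50000, n, TRUE),
    copy_number = sample(c(0, 1, 2, 3, 5, 8), n, TRUE),
    het_snp_count = sample.int(40, n, TRUE) - 1L,
    junction_supported = runif(n) < 0.15)
  high_oracle <- ((s$end - s$start >= 10000) & s$het_snp_count >= 10) |
    s$copy_number == 0 | s$copy_number >= 5 | s$junction_supported
  expect_equal(classify_segment_confidence(s)$confidence,
               ifelse(high_oracle, "high", "low"))
})

test_that("exon coverage ratios normalise by the sample mean depth", {
  cov <- tibble::tibble(sample_id = "S1", gene = "G", exon = 1:3,
                        depth = c(150, 300, 600), sample_mean_depth = 300)
  expect_equal(exon_coverage_ratio(cov)$ratio, c(0.5, 1, 2))
  cov311 <- tibble::tibble(sample_id = "S1", gene = "G", exon = 1L,
                           depth = 311, sample_mean_depth = 311)
  expect_equal(exon_coverage_ratio(cov311)$ratio, 1)
  cov0 <- tibble::tibble(sample_id = "S1", gene = "G", exon = 1:2,
                         depth = c(0, 300), sample_mean_depth = 300)
  expect_equal(exon_coverage_ratio(cov0)$ratio[1], 0)
  bad <- tibble::tibble(sample_id = "S1", gene = "G", exon = 1L,
                        depth = 0, sample_mean_depth = 0)
  expect_error(exon_coverage_ratio(bad), "positive")
})

test_that("coverage CNV calls follow thresholds, runs and precedence", {
  mk <- function(r) tibble::tibble(sample_id = "S1", gene = "G",
                                   exon = seq_along(r), ratio = r)
  hom <- call_coverage_cnv(mk(rep(0.02, 6)), normalize = FALSE)
  expect_equal(hom$call, "homozygous_deletion")
  expect_equal(c(hom$exon_start, hom$exon_end), c(1L, 6L))

  dup <- call_coverage_cnv(mk(c(1, 1, 2.1, 2.0, 1.9, 1)), normalize = FALSE)
  expect_equal(dup$call, "intragenic_duplication")
  expect_equal(c(dup$exon_start, dup$exon_end), c(3L, 5L))

  hemi <- call_coverage_cnv(mk(c(1, 0.5, 0.55, 1, 1, 1)), normalize = FALSE)
  expect_equal(hemi$call, "hemizygous_deletion")
  expect_equal(c(hemi$exon_start, hemi$exon_end), c(2L, 3L))

  expect_equal(call_coverage_cnv(mk(rep(1, 6)), normalize = FALSE)$call, "normal")
  # a single low or high exon is not a run
  expect_equal(call_coverage_cnv(mk(c(1, 0.5, 1, 1, 1, 1)), normalize = FALSE)$call, "normal")
  # precedence: homozygous beats a duplication run elsewhere
  both <- call_coverage_cnv(mk(c(0.02, 0.02, 0.02, 0.02, 1.8, 1.8)),
                            normalize = FALSE)
  expect_equal(both$call, "homozygous_deletion")

  expect_error(call_coverage_cnv(mk(rep(1, 3)), t_hom = 0.8, t_hemi = 0.7),
               "t_hom < t_hemi")
})

test_that("an event-free cohort is called normal almost everywhere", {
  cfg <- cohort_config(n_tumors = 25, n_cell_lines = 5,
                       stag2_truncating_fraction = 0,
                       stag2_duplication_fraction = 0,
                       stag2_exon_deletion_fraction = 0,
                       stag2_expression_loss_fraction = 0,
                       cdkn2a_deletion_fraction = 0,
                       tp53_mutation_fraction = 0,
                       seed = 55)
  co <- simulate_cohort(cfg)
  calls <- call_coverage_cnv(exon_coverage_ratio(co$coverage))
  expect_gte(mean(calls$call == "normal"), 0.95)
})
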