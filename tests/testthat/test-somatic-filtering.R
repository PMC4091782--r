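test_that("panel-of-normals removal is a set difference on normalised keys", {
  v <- make_variants(5, chrom = paste0("chr", 1:5), pos = 100:104)
  pon <- v[c(2, 4), c("chrom", "pos", "ref", "alt")]
  out <- remove_panel_of_normals(v, pon)
  expect_equal(nrow(out), 3L)
  expect_equal(out$chrom, c("chr1", "chr3", "chr5"))  # order preserved

  expect_equal(remove_panel_of_normals(v, pon[0, ]), tibble::as_tibble(v))
  expect_equal(nrow(remove_panel_of_normals(v, v)), 0L)
  expect_equal(nrow(remove_panel_of_normals(make_variants(0), pon)), 0L)
})

test_that("key normalisation matches padded and trimmed indel spellings", {
  # same deletion written padded (pos 100 ACT>A) and pre-trimmed (pos 101 CT>"")
  # is not legal VCF untrimmed; instead compare right-padded spellings
  a <- make_variants(1, pos = 100L, ref = "ACT", alt = "A")
  pon <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "ACTG", alt = "AG")
  expect_equal(nrow(remove_panel_of_normals(a, pon)), 0L)
  # prefix trimming advances the position
  b <- make_variants(1, pos = 100L, ref = "TA", alt = "TG")
  expect_equal(variant_keys(b), "chr1:101:A:G")
})

test_that("score filter keeps calls at or above cutoff plus verified calls", {
  v <- make_variants(3, somatic_score = c(5, 3, 2))
  out <- filter_by_somatic_score(v, cutoff = 3)
  expect_equal(out$somatic_score, c(5, 3))  # "at or above" is inclusive

  v2 <- make_variants(1, somatic_score = 1, verified = "true")
  expect_equal(nrow(filter_by_somatic_score(v2, cutoff = 3)), 1L)

  expect_equal(nrow(filter_by_somatic_score(v, cutoff = -Inf)), 3L)
})

test_that("PON and score filters commute (both are per-variant predicates)", {
  set.seed(42)
  v <- make_variants(20, chrom = sample(paste0("chr", 1:3), 20, TRUE),
                     pos = sample.int(1000, 20),
                     somatic_score = rnorm(20, 3, 4))
  pon <- v[sample.int(20, 6), c("chrom", "pos", "ref", "alt")]
  ab <- filter_by_somatic_score(remove_panel_of_normals(v, pon), 3)
  ba <- remove_panel_of_normals(filter_by_somatic_score(v, 3), pon)
  expect_equal(ab, ba)
})

test_that("calibration reproduces a hand-computed confusion matrix", {
  labeled <- tibble::tibble(
    somatic_score = c(10, 8, 5, 3, 2, 1, 0, -5),
    truth = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  cal <- calibrate_cutoff(labeled, cutoffs = 3)
  row <- cal$table[cal$table$cutoff == 3, ]
  expect_equal(row$sensitivity, 0.75)
  expect_equal(row$specificity, 0.75)
})

test_that("calibration columns match brute force and are monotone", {
  set.seed(7)
  for (rep in 1:5) {
    labeled <- tibble::tibble(
      somatic_score = rnorm(60, mean = rep(c(6, -1), each = 30), sd = 3),
      truth = rep(c(TRUE, FALSE), each = 30))
    cal <- calibrate_cutoff(labeled)
    # independent brute-force confusion matrix per cutoff
    for (i in sample.int(nrow(cal$table), 10)) {
      c <- cal$table$cutoff[i]
      pred <- labeled$somatic_score >= c
      expect_equal(cal$table$sensitivity[i],
                   sum(pred & labeled$truth) / sum(labeled$truth))
      expect_equal(cal$table$specificity[i],
                   sum(!pred & !labeled$truth) / sum(!labeled$truth))
    }
    expect_true(all(diff(cal$table$sensitivity) <= 1e-12))
    expect_true(all(diff(cal$table$specificity) >= -1e-12))
  }
})

test_that("perfect separation yields a cutoff with sensitivity = specificity = 1", {
  labeled <- tibble::tibble(somatic_score = c(10, 9, 8, -1, -2, -3),
                            truth = rep(c(TRUE, FALSE), each = 3))
  cal <- calibrate_cutoff(labeled)
  at <- glance(cal)
  expect_equal(at$sensitivity, 1)
  expect_equal(at$specificity, 1)
})

test_that("calibration rejects single-class labels", {
  expect_error(
    calibrate_cutoff(tibble::tibble(somatic_score = 1:3, truth = rep(TRUE, 3))),
    "true and one false")
})

test_that("rare protein-altering filter applies consequence and frequency rules", {
  v <- make_variants(
    5,
    consequence = c("missense", "missense", "synonymous", "nonsense", "UTR3"),
    population_af = c(0.001, 0.01, NA, NA, NA))
  out <- rare_coding_filter(v, af_threshold = 0.005)
  # missense af 0.001 kept, missense 0.01 removed, synonymous removed,
  # nonsense unreported kept, UTR3 removed
  expect_equal(out$consequence, c("missense", "nonsense"))
  expect_equal(out$population_af, c(0.001, NA))
  expect_equal(nrow(rare_coding_filter(make_variants(0))), 0L)
  expect_error(rare_coding_filter(v, af_threshold = 0), "0, 1")
})

test_that("filters equal brute-force predicate evaluation on small inputs", {
  set.seed(11)
  v <- make_variants(
    15,
    somatic_score = runif(15, -5, 10),
    consequence = sample(CONSEQUENCE_LEVELS, 15, TRUE),
    population_af = ifelse(runif(15) < 0.5, runif(15, 0, 0.02), NA))
  keep_score <- vapply(seq_len(15), function(i) v$somatic_score[i] >= 3, logical(1))
  expect_equal(filter_by_somatic_score(v, 3)$pos, v$pos[keep_score])
  keep_rare <- vapply(seq_len(15), function(i) {
    v$consequence[i] %in% c("missense", "nonsense", "frameshift",
                            "inframe_indel", "splice_site") &&
      (is.na(v$population_af[i]) || v$population_af[i] < 0.005)
  }, logical(1))
  expect_equal(rare_coding_filter(v)$pos, v$pos[keep_rare])
})

test_that("mutation rate is count scaled to the megabase", {
  expect_equal(mutation_rate(6, 4.0e7), 0.15)
  expect_equal(mutation_rate(0, 4.0e7), 0)
  expect_equal(mutation_rate(361, 2.407e9), 0.15, tolerance = 1e-3)
  expect_error(mutation_rate(5, 0), "positive")
})
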