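long_expr <- function(values, genes = "G", samples = NULL, value = "log2_fpkm") {
  if (is.null(samples)) samples <- sprintf("S%d", seq_along(values))
  out <- tidyr::expand_grid(gene = genes, sample_id = samples)
  out[[value]] <- values
  out
}

test_that("exon RPKM evaluates the normalisation formula exactly", {
  expect_equal(exon_rpkm(0, 500, 2e7), 0)
  expect_equal(exon_rpkm(200, 500, 2e7), 20)
  # homogeneity: doubling the library halves RPKM
  expect_equal(exon_rpkm(200, 500, 4e7), 10)
  expect_error(exon_rpkm(10, 0, 2e7), "positive")
  expect_error(exon_rpkm(10, 100, 0), "positive")
})

test_that("exon RPKM matches independent re-evaluation on random triples", {
  set.seed(99)
  r <- rpois(1000, 200)
  f <- sample(50:5000, 1000, TRUE)
  R <- sample(1e6:5e7, 1000, TRUE)
  # independent oracle: evaluate numerator and denominator separately
  oracle <- vapply(seq_len(1000),
                   function(i) (r[i] / f[i]) / (R[i] / 1e9),
                   numeric(1))
  got <- exon_rpkm(r, f, R)
  expect_lt(max(abs(got - oracle) / pmax(oracle, .Machine$double.eps)), 1e-9)
})

test_that("median normalisation subtracts the panel per-feature median", {
  panel <- long_expr(c(4, 5, 6), samples = c("N1", "N2", "N3"))
  x <- long_expr(7, samples = "T1")
  expect_equal(median_normalize(x, panel)$normalized, 2)
  x2 <- long_expr(3.5, samples = "T1")
  expect_equal(median_normalize(x2, panel)$normalized, -1.5)
  x3 <- long_expr(5, samples = "T1")
  expect_equal(median_normalize(x3, panel)$normalized, 0)
  bad <- long_expr(1, genes = "MISSING", samples = "T1")
  expect_error(median_normalize(bad, panel), "MISSING")
})

test_that("z-scores standardise against panel mean and SD, masking zero-SD features", {
  panel <- tibble::tibble(gene = "G", exon = 1L,
                          sample_id = c("N1", "N2", "N3"),
                          log2_rpkm = c(3, 5, 7))  # mean 5, sd 2
  x <- tibble::tibble(gene = "G", exon = 1L, sample_id = "T1", log2_rpkm = 1)
  expect_equal(exon_zscores(x, panel)$z, -2)
  x2 <- tibble::tibble(gene = "G", exon = 1L, sample_id = "T1", log2_rpkm = 5)
  expect_equal(exon_zscores(x2, panel)$z, 0)

  flat <- tibble::tibble(gene = "G", exon = 2L,
                         sample_id = c("N1", "N2"), log2_rpkm = c(4, 4))
  z <- exon_zscores(dplyr::mutate(x, exon = 2L), flat)
  expect_true(is.na(z$z))
  expect_equal(nrow(attr(z, "masked_features")), 1L)
})

test_that("panel z-scored against itself is centred per feature", {
  set.seed(5)
  panel <- tidyr::expand_grid(gene = c("A", "B"), exon = 1:3,
                              sample_id = sprintf("N%02d", 1:20)) |>
    dplyr::mutate(log2_rpkm = rnorm(dplyr::n(), 5, 1))
  z <- exon_zscores(panel, panel)
  centred <- dplyr::summarise(dplyr::group_by(z, gene, exon),
                              m = mean(z), .groups = "drop")
  expect_lt(max(abs(centred$m)), 1e-9)
})

test_that("expression-loss flags track the threshold and mutant reference", {
  z <- tidyr::expand_grid(gene = "STAG2", exon = 1:4,
                          sample_id = c("MUT1", "MUT2", "LOW", "OK")) |>
    dplyr::mutate(z = dplyr::case_when(
      sample_id %in% c("MUT1", "MUT2") ~ -3,
      sample_id == "LOW" ~ -2.9,
      TRUE ~ 0))
  out <- call_expression_loss(z, "STAG2",
                              mutant_reference = c("MUT1", "MUT2"))
  expect_true(out$flagged[out$sample_id == "LOW"])
  expect_false(out$flagged[out$sample_id == "OK"])
  # mutant reference only relaxes the threshold upward, never below -2
  expect_equal(unique(out$threshold), -2)

  allok <- dplyr::mutate(z, z = 0)
  expect_false(any(call_expression_loss(allok, "STAG2")$flagged))
})

test_that("contiguous exon-loss runs are maximal and classified by extent", {
  mk <- function(zv) tibble::tibble(gene = "G", exon = seq_along(zv),
                                    sample_id = "S1", z = zv)
  run <- detect_contiguous_exon_loss(mk(c(0, -3, -3, -3, 0)))
  expect_equal(nrow(run), 1L)
  expect_equal(c(run$exon_start, run$exon_end), c(2L, 4L))
  expect_equal(run$type, "contiguous")

  whole <- detect_contiguous_exon_loss(mk(rep(-3, 5)))
  expect_equal(whole$type, "whole_gene")
  expect_equal(c(whole$exon_start, whole$exon_end), c(1L, 5L))

  focal <- detect_contiguous_exon_loss(mk(c(0, -3, 0, 0, 0)))
  expect_equal(focal$type, "focal")
  expect_equal(focal$n_exons, 1L)

  none <- detect_contiguous_exon_loss(mk(rep(0, 5)))
  expect_equal(nrow(none), 0L)
})

test_that("Welch comparison matches the textbook formula and is symmetric", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6, 7, 8),
                      g = rep(c("a", "b"), each = 4))
  out <- compare_groups(d, v, g)
  expect_equal(out$statistic, -4.3818, tolerance = 1e-4)
  expect_equal(out$df, 6)

  # hand-written Welch oracle on random inputs
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), 0, 1)
    b <- rnorm(sample(3:12, 1), 0.8, 2)
    dd <- tibble::tibble(v = c(a, b),
                         g = rep(c("a", "b"), c(length(a), length(b))))
    got <- compare_groups(dd, v, g)
    se2a <- stats::var(a) / length(a); se2b <- stats::var(b) / length(b)
    t_or <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
    df_or <- (se2a + se2b)^2 /
      (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
    p_or <- 2 * stats::pt(-abs(t_or), df_or)
    expect_equal(got$statistic, t_or, tolerance = 1e-9)
    expect_equal(got$df, df_or, tolerance = 1e-9)
    expect_equal(got$p_value, p_or, tolerance = 1e-9)
    # swapping the groups negates t, p unchanged
    swapped <- compare_groups(dd, v, factor(g, levels = c("b", "a")))
    expect_equal(swapped$statistic, -got$statistic)
    expect_equal(swapped$p_value, got$p_value)
  }

  same <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3),
                         g = rep(c("a", "b"), each = 3))
  out2 <- compare_groups(same, v, g)
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p_value, 1)

  const <- tibble::tibble(v = rep(2, 6), g = rep(c("a", "b"), each = 3))
  expect_equal(compare_groups(const, v, g)$p_value, 1)
  expect_error(compare_groups(tibble::tibble(v = 1:3, g = c("a", "a", "b")),
                              v, g), "two observations")
})

test_that("signature score is the mean over signature genes", {
  norm <- tidyr::expand_grid(gene = c("SIG1", "SIG2", "OTHER"),
                             sample_id = c("S1", "S2")) |>
    dplyr::mutate(normalized = ifelse(gene == "OTHER", 0,
                                      ifelse(sample_id == "S1", 2, 0)))
  sc <- signature_score(norm, c("SIG1", "SIG2"))
  expect_equal(sc$score[sc$sample_id == "S1"], 2)
  expect_equal(sc$score[sc$sample_id == "S2"], 0)
  expect_error(signature_score(norm, "ABSENT"), "no signature gene")
})

test_that("Ward clustering merges the closest pair first and is permutation-stable", {
  norm <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 3),
    sample_id = rep(c("A", "B", "C"), 2),
    normalized = c(0, 1, 10, 0, 0, 0))  # d(A,B)=1, d(A,C)=10, d(B,C)=9
  cl <- cluster_samples(norm, k = 2)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))  # {A,B} merge first
  lab <- tidy(cl)
  expect_equal(lab$cluster[lab$sample_id == "A"],
               lab$cluster[lab$sample_id == "B"])
  expect_false(lab$cluster[lab$sample_id == "C"] ==
                 lab$cluster[lab$sample_id == "A"])

  dup <- tibble::tibble(gene = c("g1", "g1"), sample_id = c("X", "Y"),
                        normalized = c(3, 3))
  expect_equal(max(cluster_samples(dup, k = 1)$hclust$height), 0)

  # relabelling samples permutes but does not change the partition
  set.seed(23)
  big <- tidyr::expand_grid(gene = sprintf("g%d", 1:5),
                            sample_id = sprintf("S%02d", 1:12)) |>
    dplyr::mutate(normalized = rnorm(dplyr::n()) +
                    ifelse(sample_id %in% sprintf("S%02d", 1:6), 3, 0))
  cl1 <- tidy(cluster_samples(big, k = 2))
  perm <- big[sample.int(nrow(big)), ]
  cl2 <- tidy(cluster_samples(perm, k = 2))
  joined <- dplyr::inner_join(cl1, cl2, by = "sample_id")
  # cluster ids may swap; co-membership must be identical
  expect_equal(outer(joined$cluster.x, joined$cluster.x, "=="),
               outer(joined$cluster.y, joined$cluster.y, "=="))
})
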