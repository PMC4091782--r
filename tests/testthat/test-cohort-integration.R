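toy_matrix <- function() {
  sheet <- tibble::tibble(
    sample_id = c("T1", "T2", "T3", "T4", "N1"),
    class = c("tumor", "tumor", "tumor", "tumor", "tumor"),
    fusion_positive = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  build_alteration_matrix(
    sample_sheet = sheet,
    variants = tibble::tibble(
      sample_id = c("T1", "T2", "N1"), gene = c("STAG2", "TP53", "STAG2"),
      consequence = c("nonsense", "missense", "nonsense")),
    cnv_calls = tibble::tibble(
      sample_id = c("T1", "T3"), gene = c("CDKN2A", "CDKN2A"),
      call = c("homozygous_deletion", "homozygous_deletion")),
    expression_loss = tibble::tibble(
      sample_id = "T4", gene = "STAG2", flagged = TRUE))
}

test_that("the alteration matrix fuses evidence streams and traps unknown samples", {
  m <- toy_matrix()
  ev <- m$evidence
  t1 <- ev[ev$sample_id == "T1", ]
  expect_setequal(paste(t1$gene, t1$evidence),
                  c("STAG2 truncating_mutation", "CDKN2A homozygous_deletion"))
  # expression loss alone counts as an alteration
  expect_equal(ev$evidence[ev$sample_id == "T4"], "expression_loss")

  sheet <- tibble::tibble(sample_id = "A", class = "tumor",
                          fusion_positive = TRUE)
  expect_error(
    build_alteration_matrix(sheet, variants = tibble::tibble(
      sample_id = "GHOST", gene = "TP53", consequence = "missense")),
    "GHOST")
})

test_that("fusion-negative samples are excluded from frequency denominators", {
  m <- toy_matrix()
  f <- summarize_frequencies(m, "STAG2", "tumor")
  # N1 carries STAG2 evidence but is fusion-negative: 2 of 4, not 3 of 5
  expect_equal(c(f$count, f$total), c(2L, 4L))
  expect_equal(f$percent, 50)
})

test_that("frequencies, union and exclusivity match brute-force set operations", {
  set.seed(77)
  n <- 80
  genes <- c("STAG2", "TP53", "CDKN2A", "BRCA2")
  sheet <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:n),
    class = sample(c("tumor", "cell_line"), n, TRUE),
    fusion_positive = runif(n) < 0.9)
  hits <- tidyr::expand_grid(sample_id = sheet$sample_id, gene = genes) |>
    dplyr::filter(runif(dplyr::n()) < 0.2)
  m <- build_alteration_matrix(
    sheet,
    variants = dplyr::mutate(hits, consequence = "nonsense"))

  for (g in genes) {
    for (cls in c("tumor", "cell_line", "all")) {
      keep <- sheet$fusion_positive & (cls == "all" | sheet$class == cls)
      expected_total <- sum(keep)
      expected_count <- length(intersect(
        sheet$sample_id[keep], hits$sample_id[hits$gene == g]))
      f <- summarize_frequencies(m, g, cls)
      expect_equal(c(f$count, f$total), c(expected_count, expected_total))
      expect_equal(f$percent,
                   sign(expected_count) *
                     floor(abs(1000 * expected_count / expected_total) + 0.5) / 10)
    }
  }

  trio <- c("STAG2", "TP53", "CDKN2A")
  u <- union_alteration_fraction(m, trio)
  altered <- unique(hits$sample_id[hits$gene %in% trio])
  expect_equal(u$count, length(intersect(sheet$sample_id[sheet$fusion_positive],
                                         altered)))
  expect_equal(u$total, sum(sheet$fusion_positive))

  me <- mutual_exclusivity(m, trio)
  per_sample <- table(hits$sample_id[hits$gene %in% trio])
  expect_equal(me$n_altered, length(per_sample))
  expect_equal(me$n_exclusive, sum(per_sample == 1))
  expect_equal(me$n_overlapping, sum(per_sample >= 2))
  expect_equal(me$n_exclusive + me$n_overlapping, me$n_altered)
})

test_that("mutual exclusivity enumerates simple cases", {
  sheet <- tibble::tibble(sample_id = sprintf("S%d", 1:6),
                          class = "tumor", fusion_positive = TRUE)
  hits <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4", "S4", "S5", "S5"),
    gene = c("A", "A", "B", "A", "B", "A", "B"),
    consequence = "missense")
  m <- build_alteration_matrix(sheet, variants = hits)
  expect_equal(unlist(mutual_exclusivity(m, c("A", "B"))),
               c(n_altered = 5L, n_exclusive = 3L, n_overlapping = 2L))
  empty <- build_alteration_matrix(sheet)
  expect_equal(unlist(mutual_exclusivity(empty, c("A", "B"))),
               c(n_altered = 0L, n_exclusive = 0L, n_overlapping = 0L))
})

test_that("Fisher enrichment reproduces cross-product odds ratios and exact p", {
  res <- fisher_enrichment(4, 51, 12, 1082)
  expect_equal(res$odds_ratio, 4 * 1082 / (51 * 12))
  expect_equal(round(res$odds_ratio, 1), 7.1)

  flat <- fisher_enrichment(5, 5, 5, 5)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  small <- fisher_enrichment(3, 1, 1, 3)
  expect_equal(small$odds_ratio, 9)
  expect_equal(small$p_value, 34 / 70)

  expect_error(fisher_enrichment(0, 0, 0, 0), "empty")
  # Haldane correction only with a zero cell
  z <- fisher_enrichment(0, 10, 5, 5)
  expect_equal(z$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
})

test_that("Fisher p matches full enumeration and fisher.test on random tables", {
  set.seed(13)
  for (i in 1:40) {
    tot <- sample(8:200, 1)
    a <- sample.int(tot, 1) - 1L
    rem <- tot - a
    b <- if (rem) sample.int(rem + 1L, 1) - 1L else 0L
    rem <- rem - b
    c <- if (rem) sample.int(rem + 1L, 1) - 1L else 0L
    d <- rem - c
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    got <- fisher_enrichment(a, b, c, d)
    # full enumeration oracle over all tables with the observed margins
    xs <- max(0, (a + b) - (b + d)):min(a + b, a + c)
    probs <- vapply(xs, function(x) {
      choose(a + c, x) * choose(b + d, (a + b) - x) / choose(tot, a + b)
    }, numeric(1))
    obs <- probs[xs == a]
    oracle <- sum(probs[probs <= obs * (1 + 1e-7)])
    expect_equal(got$p_value, oracle, tolerance = 1e-9)
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    expect_equal(got$p_value, ft$p.value, tolerance = 1e-7)
  }
})

test_that("oncoprint export is deterministically ordered and complete", {
  m <- toy_matrix()
  long <- export_oncoprint(m)
  expect_equal(nrow(long), nrow(m$evidence))
  # T1 has 2 altered genes and leads; ties broken by sample id
  expect_equal(long$sample_id[long$sample_order == 1], rep("T1", 2))
  burden <- table(long$sample_id)
  ord <- dplyr::distinct(long, sample_id, sample_order)
  expect_equal(ord$sample_order, sort(ord$sample_order))

  one <- build_alteration_matrix(
    tibble::tibble(sample_id = "S1", class = "tumor", fusion_positive = TRUE),
    variants = tibble::tibble(sample_id = "S1", gene = "TP53",
                              consequence = "missense"))
  expect_equal(nrow(export_oncoprint(one)), 1L)
})
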