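#' Alteration evidence vocabulary
#' @export
EVIDENCE_LEVELS <- c("point_mutation", "truncating_mutation",
                     "structural_variant", "homozygous_deletion",
                     "intragenic_duplication", "expression_loss")

consequence_to_evidence <- function(consequence) {
  dplyr::case_when(
    consequence %in% c("nonsense", "frameshift", "splice_site") ~
      "truncating_mutation",
    consequence %in% c("missense", "inframe_indel") ~ "point_mutation",
    TRUE ~ NA_character_
  )
}

#' Build a sample-by-gene alteration matrix
#'
#' Fuses per-sample evidence streams — filtered protein-altering variant
#' calls, coverage-based CNV calls, and expression-loss flags — into one
#' long evidence table (the oncoprint backbone). A gene counts as altered
#' in a sample when its evidence set is non-empty. Samples lacking a
#' TET-ETS fusion are retained in the matrix but flagged, and are excluded
#' from every frequency denominator by the summary operations, since such
#' samples are molecularly distinct from fusion-positive EFT.
#'
#' @param sample_sheet Tibble with `sample_id`, `class` (`"tumor"` /
#'   `"cell_line"`), `fusion_positive` (logical), and optionally `assays`
#'   — a comma-separated list of genes assayed (empty/`NA` meaning all).
#' @param variants Filtered variant calls (`sample_id`, `gene`,
#'   `consequence`); only protein-altering consequences contribute.
#' @param cnv_calls Coverage CNV calls (`sample_id`, `gene`, `call`), as
#'   from [call_coverage_cnv()]; `normal` calls contribute nothing.
#' @param expression_loss Expression-loss flags (`sample_id`, `gene`,
#'   `flagged`), e.g. from [call_expression_loss()] results.
#' @param structural_variants Optional junction-supported events
#'   (`sample_id`, `gene`).
#' @return An object of class `eft_alteration_matrix`: a list with
#'   `evidence` (long tibble `sample_id`, `gene`, `evidence`) and
#'   `samples` (the sample sheet with an `assayed_genes` list-column).
#' @export
build_alteration_matrix <- function(sample_sheet, variants = NULL,
                                    cnv_calls = NULL,
                                    expression_loss = NULL,
                                    structural_variants = NULL) {
  check_columns(sample_sheet, c("sample_id", "class", "fusion_positive"),
                "sample_sheet")
  known <- sample_sheet$sample_id

  pieces <- list()
  if (!is.null(variants) && nrow(variants)) {
    check_columns(variants, c("sample_id", "gene", "consequence"), "variants")
    pieces$variants <- as_tibble(variants) |>
      mutate(evidence = consequence_to_evidence(.data$consequence)) |>
      filter(!is.na(.data$evidence)) |>
      select("sample_id", "gene", "evidence")
  }
  if (!is.null(cnv_calls) && nrow(cnv_calls)) {
    check_columns(cnv_calls, c("sample_id", "gene", "call"), "cnv_calls")
    pieces$cnv <- as_tibble(cnv_calls) |>
      filter(.data$call %in% c("homozygous_deletion",
                               "intragenic_duplication")) |>
      mutate(evidence = .data$call) |>
      select("sample_id", "gene", "evidence")
  }
  if (!is.null(expression_loss) && nrow(expression_loss)) {
    check_columns(expression_loss, c("sample_id", "gene", "flagged"),
                  "expression_loss")
    pieces$expr <- as_tibble(expression_loss) |>
      filter(.data$flagged) |>
      mutate(evidence = "expression_loss") |>
      select("sample_id", "gene", "evidence")
  }
  if (!is.null(structural_variants) && nrow(structural_variants)) {
    check_columns(structural_variants, c("sample_id", "gene"),
                  "structural_variants")
    pieces$sv <- as_tibble(structural_variants) |>
      mutate(evidence = "structural_variant") |>
      select("sample_id", "gene", "evidence")
  }

  evidence <- if (length(pieces)) distinct(bind_rows(pieces)) else
    tibble(sample_id = character(), gene = character(),
           evidence = character())

  unknown <- setdiff(evidence$sample_id, known)
  if (length(unknown)) {
    abort(sprintf("evidence for sample id(s) not in the sample sheet: %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  bad <- setdiff(evidence$evidence, EVIDENCE_LEVELS)
  if (length(bad)) {
    abort(sprintf("unknown evidence label(s): %s", paste(bad, collapse = ", ")))
  }

  samples <- as_tibble(sample_sheet)
  if (!"assays" %in% names(samples)) samples$assays <- NA_character_
  samples$assayed_genes <- lapply(samples$assays, function(a) {
    if (is.na(a) || !nzchar(a)) NULL else strsplit(a, ",", fixed = TRUE)[[1]]
  })

  structure(list(evidence = evidence, samples = samples),
            class = "eft_alteration_matrix")
}

#' @export
print.eft_alteration_matrix <- function(x, ...) {
  cat(sprintf("Alteration matrix: %d samples (%d fusion-positive), %d genes, %d evidence entries\n",
              nrow(x$samples), sum(x$samples$fusion_positive),
              dplyr::n_distinct(x$evidence$gene), nrow(x$evidence)))
  invisible(x)
}

# was this sample assayed for this gene?
sample_assayed <- function(samples, gene) {
  vapply(samples$assayed_genes, function(g) is.null(g) || gene %in% g,
         logical(1))
}

altered_samples <- function(matrix, gene) {
  unique(matrix$evidence$sample_id[matrix$evidence$gene == gene])
}

#' Mutational frequency of a gene in a sample class
#'
#' Percent of fusion-positive samples of the class, assayed for the gene,
#' that carry any alteration of the gene. Percent is rounded to one
#' decimal, half away from zero, as in printed frequency tables.
#'
#' @param matrix An [build_alteration_matrix()] result.
#' @param gene Gene symbol.
#' @param sample_class `"tumor"`, `"cell_line"`, or `"all"`.
#' @return One-row tibble: `gene`, `sample_class`, `count`, `total`,
#'   `percent`.
#' @export
summarize_frequencies <- function(matrix, gene, sample_class = "all") {
  samples <- matrix$samples
  if (sample_class != "all") samples <- samples[samples$class == sample_class, ]
  samples <- samples[samples$fusion_positive & sample_assayed(samples, gene), ]
  if (nrow(samples) == 0L) {
    abort(sprintf("no fusion-positive %s samples assayed for %s",
                  sample_class, gene))
  }
  count <- sum(samples$sample_id %in% altered_samples(matrix, gene))
  tibble(gene = gene, sample_class = sample_class,
         count = count, total = nrow(samples),
         percent = round_half_up(100 * count / nrow(samples), 1))
}

#' Fraction of samples altered in at least one of a gene set
#'
#' Counts fusion-positive samples, assayed for every listed gene, that are
#' altered in at least one of them (e.g. STAG2, TP53 or CDKN2A).
#'
#' @inheritParams summarize_frequencies
#' @param genes Character vector of genes.
#' @return One-row tibble: `count`, `total`, `percent`.
#' @export
union_alteration_fraction <- function(matrix, genes, sample_class = "all") {
  samples <- matrix$samples
  if (sample_class != "all") samples <- samples[samples$class == sample_class, ]
  samples <- samples[samples$fusion_positive, ]
  for (g in genes) samples <- samples[sample_assayed(samples, g), ]
  altered <- unique(matrix$evidence$sample_id[matrix$evidence$gene %in% genes])
  count <- sum(samples$sample_id %in% altered)
  tibble(count = count, total = nrow(samples),
         percent = if (nrow(samples)) round_half_up(100 * count / nrow(samples), 1) else NA_real_)
}

#' Mutual exclusivity of alterations across a gene set
#'
#' Among samples altered in at least one of the genes, counts those
#' altered in exactly one (exclusive) versus two or more (overlapping).
#' `n_exclusive + n_overlapping = n_altered` always.
#'
#' @inheritParams union_alteration_fraction
#' @return One-row tibble: `n_altered`, `n_exclusive`, `n_overlapping`.
#' @export
mutual_exclusivity <- function(matrix, genes, sample_class = "all") {
  if (length(genes) < 2L) abort("mutual exclusivity needs >= 2 genes")
  samples <- matrix$samples
  if (sample_class != "all") samples <- samples[samples$class == sample_class, ]
  ev <- matrix$evidence |>
    filter(.data$gene %in% genes,
           .data$sample_id %in% samples$sample_id) |>
    distinct(.data$sample_id, .data$gene) |>
    dplyr::count(.data$sample_id, name = "n_genes")
  tibble(n_altered = nrow(ev),
         n_exclusive = sum(ev$n_genes == 1L),
         n_overlapping = sum(ev$n_genes >= 2L))
}

#' Fisher exact enrichment for a 2x2 table
#'
#' Odds ratio and two-tailed Fisher exact p-value for a 2x2 contingency
#' table in exposed-case / exposed-control layout (`a` = exposed cases,
#' `b` = unexposed cases, `c` = exposed controls, `d` = unexposed
#' controls). The odds ratio is the plain cross-product `(a d)/(b c)`;
#' the Haldane correction (+0.5 to every cell) is applied only when a zero
#' cell occurs. The two-tailed p-value is computed by the method of small
#' p-values: the sum, over all tables with the observed margins, of
#' hypergeometric probabilities no larger than that of the observed table.
#'
#' @param a,b,c,d Non-negative integer cell counts; alternatively pass a
#'   2x2 matrix as `a`.
#' @return One-row tibble: `odds_ratio`, `p_value`, and the four cells.
#' @examples
#' # K3326X carriers: 4 of 55 patients vs 12 of 1094 population controls
#' fisher_enrichment(4, 51, 12, 1082)
#' @export
fisher_enrichment <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != trunc(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) abort("the contingency table is empty")

  if (any(cells == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }

  # hypergeometric enumeration over tables with the observed margins:
  # x = exposed cases, with m = a + c exposed, n = b + d unexposed,
  # k = a + b cases drawn
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  p <- min(1, p)

  tibble(odds_ratio = or, p_value = p, a = a, b = b, c = c, d = d)
}

#' Export an alteration matrix in oncoprint long format
#'
#' One row per (sample, gene, evidence), with a deterministic sample
#' ordering: by class, then by number of altered genes (descending), then
#' by sample id. The `sample_order` integer column gives each sample's
#' display position.
#'
#' @param matrix An [build_alteration_matrix()] result with at least one
#'   sample.
#' @return Long tibble: `sample_id`, `class`, `fusion_positive`, `gene`,
#'   `evidence`, `sample_order`.
#' @export
export_oncoprint <- function(matrix) {
  if (nrow(matrix$samples) == 0L) abort("the alteration matrix is empty")
  burden <- matrix$evidence |>
    distinct(.data$sample_id, .data$gene) |>
    dplyr::count(.data$sample_id, name = "n_altered_genes")
  order_tbl <- matrix$samples |>
    select("sample_id", "class", "fusion_positive") |>
    left_join(burden, by = "sample_id") |>
    mutate(n_altered_genes = dplyr::coalesce(.data$n_altered_genes, 0L)) |>
    arrange(.data$class, dplyr::desc(.data$n_altered_genes),
            .data$sample_id) |>
    mutate(sample_order = row_number())
  matrix$evidence |>
    dplyr::inner_join(order_tbl, by = "sample_id") |>
    arrange(.data$sample_order, .data$gene, .data$evidence) |>
    select("sample_id", "class", "fusion_positive", "gene", "evidence",
           "sample_order")
}
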