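#' Exon-level RPKM
#'
#' Reads per kilobase of exon per million mapped reads:
#' `RPKM = (r * 1e9) / (f * R)`, with `r` the reads mapped to the exon,
#' `f` the exon length in bases and `R` the sample's total mapped reads.
#' Vectorised over all three arguments.
#'
#' @param r Read count(s) mapped to the exon.
#' @param f Exon length(s) in bases; must be positive.
#' @param R Total mapped read count(s) of the sample; must be positive.
#' @return Numeric RPKM values.
#' @examples
#' exon_rpkm(200, 500, 2e7)  # 20
#' @export
exon_rpkm <- function(r, f, R) {
  if (any(f <= 0)) abort("exon length `f` must be positive")
  if (any(R <= 0)) abort("library size `R` must be positive")
  if (any(r < 0)) abort("read count `r` must be non-negative")
  # double arithmetic: f * R overflows integer storage for real libraries
  (as.numeric(r) * 1e9) / (as.numeric(f) * as.numeric(R))
}

#' Add RPKM and log2 layers to an exon count table
#'
#' @param exon_counts Long tibble with columns `gene`, `exon`,
#'   `exon_length`, `sample_id`, `count`, `library_size`.
#' @param offset Added inside the log2 to handle zero counts (default 1).
#' @return Input with `rpkm` and `log2_rpkm` columns added.
#' @export
add_exon_rpkm <- function(exon_counts, offset = 1) {
  check_columns(exon_counts,
                c("gene", "exon", "exon_length", "sample_id", "count",
                  "library_size"),
                "exon_counts")
  mutate(as_tibble(exon_counts),
         rpkm = exon_rpkm(.data$count, .data$exon_length,
                          .data$library_size),
         log2_rpkm = log2(.data$rpkm + offset))
}

panel_feature_stats <- function(panel, feature_cols, value_col) {
  panel |>
    group_by(across(dplyr::all_of(feature_cols))) |>
    summarise(
      panel_median = median(.data[[value_col]]),
      panel_mean = mean(.data[[value_col]]),
      panel_sd = sd(.data[[value_col]]),
      panel_n = dplyr::n(),
      .groups = "drop"
    )
}

check_panel_features <- function(x, stats, feature_cols) {
  missing <- anti_join(distinct(x, across(dplyr::all_of(feature_cols))),
                       stats, by = feature_cols)
  if (nrow(missing)) {
    lab <- do.call(paste, c(missing[1, feature_cols, drop = FALSE],
                            list(sep = ":")))
    abort(sprintf("feature %s is absent from the reference panel", lab))
  }
  if (any(stats$panel_n < 2L)) {
    abort("the reference panel needs >= 2 samples per feature")
  }
  invisible(stats)
}

#' Median-normalise expression against a normal-tissue panel
#'
#' Subtracts, feature by feature, the median log2 expression of a reference
#' panel of normal tissue samples, putting tumour values on a scale where 0
#' means "typical normal tissue".
#'
#' @param x Long tibble of log2 expression with a feature column (`gene`,
#'   or `gene` + `exon`), `sample_id`, and the value column.
#' @param panel Reference panel in the same shape (>= 2 samples per
#'   feature).
#' @param value Name of the value column (default `"log2_fpkm"`).
#' @return `x` with `panel_median` and `normalized` columns added.
#' @export
median_normalize <- function(x, panel, value = "log2_fpkm") {
  feature_cols <- intersect(c("gene", "exon"), names(x))
  if (!length(feature_cols)) abort("`x` needs a `gene` (and optionally `exon`) column")
  check_columns(x, c(feature_cols, "sample_id", value), "x")
  check_columns(panel, c(feature_cols, "sample_id", value), "panel")
  stats <- panel_feature_stats(panel, feature_cols, value)
  check_panel_features(x, stats, feature_cols)
  as_tibble(x) |>
    left_join(select(stats, dplyr::all_of(c(feature_cols, "panel_median"))),
              by = feature_cols) |>
    mutate(normalized = .data[[value]] - .data$panel_median)
}

#' Per-exon z-scores against the normal panel
#'
#' Standardises log2 expression per feature against the reference panel's
#' mean and standard deviation: `z = (value - panel mean) / panel SD`.
#' Typically applied to `log2(RPKM + 1)` exon values; the z-score is
#' invariant to the prior median normalisation (a per-feature shift).
#' Features with zero panel SD cannot be standardised and are masked
#' (`z = NA`), with the masked features recorded in the
#' `"masked_features"` attribute.
#'
#' @inheritParams median_normalize
#' @param value Name of the value column (default `"log2_rpkm"`).
#' @return `x` with `panel_mean`, `panel_sd`, `normalized` (value minus
#'   panel median) and `z` columns added.
#' @export
exon_zscores <- function(x, panel, value = "log2_rpkm") {
  feature_cols <- intersect(c("gene", "exon"), names(x))
  if (!length(feature_cols)) abort("`x` needs a `gene` (and optionally `exon`) column")
  check_columns(x, c(feature_cols, "sample_id", value), "x")
  check_columns(panel, c(feature_cols, "sample_id", value), "panel")
  stats <- panel_feature_stats(panel, feature_cols, value)
  check_panel_features(x, stats, feature_cols)
  out <- as_tibble(x) |>
    left_join(stats, by = feature_cols) |>
    mutate(
      normalized = .data[[value]] - .data$panel_median,
      z = ifelse(.data$panel_sd > 0,
                 (.data[[value]] - .data$panel_mean) / .data$panel_sd,
                 NA_real_)
    ) |>
    select(-"panel_n")
  masked <- distinct(filter(out, is.na(.data$z)),
                     across(dplyr::all_of(feature_cols)))
  attr(out, "masked_features") <- masked
  out
}

#' Flag samples with expression loss of a gene
#'
#' Flags samples whose gene-median exon z-score is at or below a threshold.
#' When a reference set of samples with known truncating mutations is
#' supplied, the threshold is relaxed to the reference median plus a
#' tolerance if that is higher than `z_threshold`, so "expression loss" is
#' read as "comparable to the truncating-mutant samples".
#'
#' @param z Long tibble of exon z-scores (columns `gene`, `exon`,
#'   `sample_id`, `z`), as from [exon_zscores()].
#' @param gene Gene to assess.
#' @param mutant_reference Character vector of sample ids with known
#'   truncating mutations (may be empty).
#' @param z_threshold Base threshold (default -2).
#' @param tolerance Allowance above the mutant-reference median
#'   (default 0.5).
#' @return Tibble with one row per sample: `median_z`, the applied
#'   `threshold`, `flagged`, and `in_reference`.
#' @export
call_expression_loss <- function(z, gene, mutant_reference = character(),
                                 z_threshold = -2, tolerance = 0.5) {
  check_columns(z, c("gene", "exon", "sample_id", "z"), "z")
  g <- gene
  zz <- filter(as_tibble(z), .data$gene == g)
  if (nrow(zz) == 0L) abort(sprintf("gene %s not present in z matrix", g))
  per_sample <- zz |>
    group_by(.data$sample_id) |>
    summarise(median_z = median(.data$z, na.rm = TRUE), .groups = "drop")
  thr <- z_threshold
  if (length(mutant_reference)) {
    ref <- per_sample$median_z[per_sample$sample_id %in% mutant_reference]
    if (length(ref)) thr <- max(z_threshold, median(ref) + tolerance)
  }
  per_sample |>
    mutate(threshold = thr,
           flagged = .data$median_z <= thr,
           in_reference = .data$sample_id %in% mutant_reference)
}

#' Detect contiguous multi-exon expression loss
#'
#' Finds, per sample and gene, maximal runs of consecutive exons whose
#' z-score is at or below the threshold. Runs of at least `min_run` exons
#' are the signature of an exonic deletion (`"contiguous"`), a run
#' covering every exon is reported as `"whole_gene"`, and an isolated
#' single low exon (below `min_run`) is reported distinctly as
#' `"focal"` single-exon loss rather than as a deletion-like run.
#'
#' @param z Long tibble of exon z-scores (`gene`, `exon`, `sample_id`, `z`).
#' @param min_run Minimum run length counted as contiguous loss (default 2).
#' @param z_threshold Loss threshold on z (default -2).
#' @return Tibble with `sample_id`, `gene`, `exon_start`, `exon_end`,
#'   `n_exons`, `type` in `{"whole_gene", "contiguous", "focal"}`.
#' @export
detect_contiguous_exon_loss <- function(z, min_run = 2, z_threshold = -2) {
  check_columns(z, c("gene", "exon", "sample_id", "z"), "z")
  as_tibble(z) |>
    arrange(.data$sample_id, .data$gene, .data$exon) |>
    group_by(.data$sample_id, .data$gene) |>
    dplyr::group_modify(function(d, key) {
      low <- !is.na(d$z) & d$z <= z_threshold
      runs <- find_runs(low)
      if (!nrow(runs)) return(tibble(exon_start = integer(), exon_end = integer(),
                                     n_exons = integer(), type = character()))
      tibble(
        exon_start = d$exon[runs$start],
        exon_end = d$exon[runs$end],
        n_exons = runs$length,
        type = dplyr::case_when(
          runs$length == nrow(d) ~ "whole_gene",
          runs$length >= min_run ~ "contiguous",
          TRUE ~ "focal"
        )
      )
    }) |>
    ungroup()
}

#' Welch two-group comparison of expression values
#'
#' Two-tailed Student t test assuming unequal variances (Welch) on log2
#' expression values, reporting the two group means on the log2 scale.
#'
#' @param data A data frame.
#' @param value Column of (log2) values.
#' @param group Column defining exactly two groups.
#' @return One-row tibble: the two group labels and means, `estimate`
#'   (mean_a - mean_b), `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  v <- rlang::eval_tidy(value, data)
  g <- rlang::eval_tidy(group, data)
  levels <- if (is.factor(g)) levels(droplevels(g)) else unique(as.character(g))
  if (length(levels) != 2L) abort("`group` must define exactly two groups")
  a <- v[as.character(g) == levels[1L]]
  b <- v[as.character(g) == levels[2L]]
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least two observations")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(group_a = levels[1L], group_b = levels[2L],
                    mean_a = mean(a), mean_b = mean(b),
                    estimate = 0, statistic = 0, df = NA_real_, p_value = 1))
    }
    abort("both groups are constant; the Welch statistic is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble(group_a = levels[1L], group_b = levels[2L],
         mean_a = mean(a), mean_b = mean(b),
         estimate = mean(a) - mean(b),
         statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Per-sample signature score
#'
#' Mean median-normalised log2 expression over a set of signature genes
#' (e.g. an Ewing sarcoma signature, or genes correlating with an
#' EWSR1-FLI1 target); fusion-positive tumours score high, fusion-negative
#' samples lack the profile.
#'
#' @param normalized Long tibble with `gene`, `sample_id` and a
#'   `normalized` value column (see [median_normalize()]).
#' @param signature Character vector of signature genes (unique,
#'   non-empty), assumed up-regulated in the disease.
#' @return Tibble with `sample_id`, `score`, `n_genes` used.
#' @export
signature_score <- function(normalized, signature) {
  check_columns(normalized, c("gene", "sample_id", "normalized"), "normalized")
  signature <- unique(signature)
  if (!length(signature)) abort("`signature` must be non-empty")
  hit <- filter(as_tibble(normalized), .data$gene %in% signature)
  if (nrow(hit) == 0L) abort("no signature gene present in the matrix")
  hit |>
    group_by(.data$sample_id) |>
    summarise(score = mean(.data$normalized),
              n_genes = dplyr::n_distinct(.data$gene),
              .groups = "drop")
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on normalised log2 expression using
#' Euclidean distance and the Ward agglomeration method
#' (`stats::hclust(method = "ward.D2")`, i.e. Ward's criterion on
#' Euclidean distances). Sample order — and hence the deterministic
#' tie-break, which merges the lowest-index pair first — follows first
#' appearance in the input.
#'
#' @param normalized Long tibble with `gene`, `sample_id` and a value
#'   column.
#' @param k Number of clusters for the dendrogram cut (default 2).
#' @param value Value column name (default `"normalized"`).
#' @return An object of class `eft_clustering`: list with the `hclust`
#'   tree, `labels` (tibble of `sample_id`, `cluster`), and `k`.
#' @export
cluster_samples <- function(normalized, k = 2, value = "normalized") {
  check_columns(normalized, c("gene", "sample_id", value), "normalized")
  wide <- as_tibble(normalized) |>
    select("gene", "sample_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "gene", values_from = dplyr::all_of(value))
  if (nrow(wide) < 2L) abort("clustering needs at least two samples")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  if (anyNA(m)) abort("expression matrix has missing values")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  structure(
    list(hclust = hc,
         labels = tibble(sample_id = names(cl), cluster = unname(cl)),
         k = k),
    class = "eft_clustering"
  )
}

#' @export
print.eft_clustering <- function(x, ...) {
  cat(sprintf("Ward/Euclidean clustering of %d samples, cut at k = %d\n",
              length(x$hclust$order), x$k))
  print(table(cluster = x$labels$cluster))
  invisible(x)
}
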