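#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a somatic-score calibration
#'
#' @param x An `eft_calibration` object.
#' @param ... Unused.
#' @return One row per candidate cutoff with confusion counts,
#'   sensitivity, specificity and Youden's J.
#' @export
tidy.eft_calibration <- function(x, ...) {
  x$table
}

#' One-row summary of a calibration's operating point
#'
#' @inheritParams tidy.eft_calibration
#' @export
glance.eft_calibration <- function(x, ...) {
  at <- x$table[x$table$cutoff == x$chosen_cutoff, ]
  tibble(chosen_cutoff = x$chosen_cutoff,
         sensitivity = at$sensitivity,
         specificity = at$specificity,
         youden_j = at$youden_j,
         n_true = x$n_true, n_false = x$n_false)
}

#' Tidy a sample clustering
#'
#' @param x An `eft_clustering` object.
#' @param ... Unused.
#' @return Tibble of `sample_id` and `cluster` assignment at the k-cut.
#' @export
tidy.eft_clustering <- function(x, ...) {
  x$labels
}

#' One-row summary of a sample clustering
#'
#' @inheritParams tidy.eft_clustering
#' @export
glance.eft_clustering <- function(x, ...) {
  tibble(n_samples = length(x$hclust$order), k = x$k,
         max_height = max(x$hclust$height))
}

#' Tidy an alteration matrix into oncoprint long format
#'
#' @param x An `eft_alteration_matrix` object.
#' @param ... Unused.
#' @export
tidy.eft_alteration_matrix <- function(x, ...) {
  export_oncoprint(x)
}

#' One-row summary of an alteration matrix
#'
#' @inheritParams tidy.eft_alteration_matrix
#' @export
glance.eft_alteration_matrix <- function(x, ...) {
  tibble(n_samples = nrow(x$samples),
         n_fusion_positive = sum(x$samples$fusion_positive),
         n_genes = dplyr::n_distinct(x$evidence$gene),
         n_evidence = nrow(x$evidence))
}
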