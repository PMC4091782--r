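#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_vline geom_segment labs theme_minimal scale_fill_gradient2
#'   scale_fill_brewer facet_grid theme element_text element_blank
#' @export
ggplot2::autoplot

#' Plot a calibration curve
#'
#' Sensitivity and specificity as a function of the somatic-score cutoff,
#' with the chosen operating point marked.
#'
#' @param object An `eft_calibration` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eft_calibration <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table,
                              c("sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$cutoff, y = .data$value,
                   colour = .data$metric)) +
    geom_line() +
    geom_point(size = 0.8) +
    geom_vline(xintercept = object$chosen_cutoff, linetype = "dashed") +
    labs(x = "somatic score cutoff", y = NULL, colour = NULL,
         title = "Somatic-score cutoff calibration",
         subtitle = sprintf("chosen cutoff: %.3g", object$chosen_cutoff)) +
    theme_minimal()
}

#' Oncoprint of an alteration matrix
#'
#' Sample-by-gene grid of alteration evidence, samples ordered by class,
#' alteration burden and id (see [export_oncoprint()]).
#'
#' @param object An `eft_alteration_matrix` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eft_alteration_matrix <- function(object, ...) {
  long <- export_oncoprint(object)
  ggplot(long, aes(x = stats::reorder(.data$sample_id, .data$sample_order),
                   y = .data$gene, fill = .data$evidence)) +
    geom_tile(colour = "white", linewidth = 0.2) +
    facet_grid(cols = ggplot2::vars(.data$class), scales = "free_x",
               space = "free_x") +
    scale_fill_brewer(palette = "Set1") +
    labs(x = NULL, y = NULL,
         title = "Alteration matrix (oncoprint)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Exon-level z-score heatmap for one gene
#'
#' Visualises median-normalised exon z-scores across samples — the view
#' in which truncating-mutant expression loss and contiguous-exon dropout
#' are read off.
#'
#' @param z Exon z-score tibble (`gene`, `exon`, `sample_id`, `z`).
#' @param gene Gene to display.
#' @return A ggplot.
#' @export
plot_exon_zscores <- function(z, gene) {
  g <- gene
  zz <- filter(as_tibble(z), .data$gene == g)
  if (!nrow(zz)) abort(sprintf("gene %s not present", g))
  ggplot(zz, aes(x = factor(.data$exon), y = .data$sample_id,
                 fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0) +
    labs(x = paste(g, "exon"), y = NULL, fill = "z",
         title = sprintf("Exon-level expression z-scores: %s", g)) +
    theme_minimal() +
    theme(axis.text.y = element_text(size = 6))
}

#' Dendrogram of a sample clustering
#'
#' @param object An `eft_clustering` object.
#' @param ... Unused.
#' @return A ggplot drawing the Ward dendrogram with cluster-coloured
#'   leaf labels.
#' @export
autoplot.eft_clustering <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  # leaf x-positions follow the dendrogram order
  segs <- dendrogram_segments(dend)
  leaves <- tibble(sample_id = hc$labels[hc$order],
                   x = seq_along(hc$order)) |>
    left_join(object$labels, by = "sample_id")
  ggplot() +
    geom_segment(data = segs,
                 aes(x = .data$x0, xend = .data$x1,
                     y = .data$y0, yend = .data$y1)) +
    geom_point(data = leaves,
               aes(x = .data$x, y = 0, colour = factor(.data$cluster))) +
    labs(x = NULL, y = "merge height", colour = "cluster",
         title = sprintf("Ward/Euclidean clustering (k = %d)", object$k)) +
    theme_minimal() +
    theme(axis.text.x = element_blank())
}

# flatten a dendrogram into line segments for ggplot
dendrogram_segments <- function(dend) {
  segs <- list()
  walk <- function(node) {
    if (is.leaf(node)) {
      return(list(x = attr(node, "x") %||% 0, y = 0))
    }
    h <- attr(node, "height")
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    xs <- vapply(kids, `[[`, numeric(1), "x")
    ys <- vapply(kids, `[[`, numeric(1), "y")
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1L]] <<- tibble(x0 = xs[i], x1 = xs[i],
                                           y0 = ys[i], y1 = h)
    }
    segs[[length(segs) + 1L]] <<- tibble(x0 = min(xs), x1 = max(xs),
                                         y0 = h, y1 = h)
    list(x = mean(range(xs)), y = h)
  }
  # assign leaf x positions in dendrogram order
  i <- 0L
  dend <- stats::dendrapply(dend, function(node) {
    if (is.leaf(node)) {
      i <<- i + 1L
      attr(node, "x") <- i
    }
    node
  })
  walk(dend)
  bind_rows(segs)
}
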