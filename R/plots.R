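#' Manhattan plot of window variance shares
#'
#' Posterior mean percentage of genetic variance per 1-Mb window along the
#' genome, with the relevance threshold drawn as a reference line.
#'
#' @param object a `gwas_fit`.
#' @param multiplier fold-over-expectation threshold to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gwas_fit <- function(object, multiplier = 5, ...) {
  w <- call_relevant_windows(object$window_table, multiplier)
  w <- dplyr::arrange(w, .data$chrom, .data$window_index)
  w$x <- seq_len(nrow(w))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$x, y = .data$prop_vg,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(w, "threshold_pct"),
                        linetype = "dashed") +
    ggplot2::labs(x = "1-Mb window (genome order)",
                  y = "genetic variance explained (%)",
                  title = sprintf("Window variance shares (threshold %.2f%%)",
                                  attr(w, "threshold_pct"))) +
    ggplot2::theme_minimal()
}

#' p-value histogram of an eQTL scan
#'
#' Diagnostic for test calibration: a well-behaved scan shows a uniform
#' bulk with a spike near zero from true associations.
#'
#' @param records eQTL tibble with `p_value` (and optionally `class`).
#' @return a ggplot object.
#' @export
plot_eqtl_pvalues <- function(records) {
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::labs(x = "p-value", y = "pairs") +
    ggplot2::theme_minimal()
  if ("class" %in% names(records))
    p <- p + ggplot2::facet_wrap(~class, scales = "free_y")
  p
}

#' Plot a regulation network
#'
#' Simple force-directed layout with SNP nodes as squares, genes as circles
#' (TFs filled), and edges coloured by the sign of the regression beta.
#'
#' @param object a `regulation_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.regulation_network <- function(object, ...) {
  lay <- igraph::layout_with_fr(object)
  nodes <- tibble::tibble(name = igraph::V(object)$name,
                          type = igraph::V(object)$type,
                          is_tf = igraph::V(object)$is_tf,
                          x = lay[, 1], y = lay[, 2])
  el <- igraph::as_data_frame(object, what = "edges")
  el$x <- nodes$x[match(el$from, nodes$name)]
  el$y <- nodes$y[match(el$from, nodes$name)]
  el$xend <- nodes$x[match(el$to, nodes$name)]
  el$yend <- nodes$y[match(el$to, nodes$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = el,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$sign)) +
    ggplot2::scale_colour_manual(values = c(positive = "grey50",
                                            negative = "red3")) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$type, fill = .data$is_tf),
                        size = 3) +
    ggplot2::scale_shape_manual(values = c(snp = 22, gene = 21)) +
    ggplot2::theme_void()
}
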