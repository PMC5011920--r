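# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.kmer_histogram <- function(object, max_multiplicity = NULL, ...) {
  h <- object$histogram
  if (!is.null(max_multiplicity)) {
    h <- h[h$multiplicity <= max_multiplicity, ]
  }
  ggplot2::ggplot(h, ggplot2::aes(
    x = .data$multiplicity, y = .data$distinct_kmers
  )) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(
      x = sprintf("%d-mer multiplicity (fold coverage)", object$k),
      y = "distinct k-mers",
      title = "k-mer depth histogram"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.histone_calls <- function(object, ...) {
  inv <- inventory(object)
  ggplot2::ggplot(inv, ggplot2::aes(
    x = .data$family, y = .data$n, fill = .data$variant
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "histone family", y = "genes",
      title = "histone complement inventory"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.histone_annotation <- function(object, ...) {
  rep <- object$report
  ggplot2::ggplot(rep, ggplot2::aes(
    x = .data$gene_id, y = .data$stability_score, fill = .data$verdict
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = stability_threshold_default(), linetype = 2
    ) +
    ggplot2::labs(
      x = NULL, y = "stem-loop stability score",
      title = "3'-UTR stem-loop stability and replication-dependency"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an alignment-free stem-loop dendrogram
#'
#' @param x A `stemloop_distances` or `ak_dendrogram`.
#' @param ... Passed to [stats::plot.hclust()].
#' @return The `hclust` object, invisibly.
#' @export
plot_dendrogram <- function(x, ...) {
  if (inherits(x, "stemloop_distances")) {
    x <- x$dendrogram
  }
  hc <- as_hclust(x)
  plot(hc, ...)
  invisible(hc)
}
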