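#' Stacked-bar composition plot
#'
#' @param comp A [composition_table()] tibble.
#' @param by Faceting columns (default `c("tissue", "method")`).
#' @return A ggplot object.
#' @export
plot_composition <- function(comp, by = c("tissue", "method")) {
  comp$dataset <- interaction(comp[by], sep = " / ")
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$dataset,
                                     y = .data$proportion,
                                     fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of cells", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' MA-style plot of a differential-expression result
#'
#' @param object A `pairseq_de` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pairseq_de
#' @export
autoplot.pairseq_de <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$base_mean + 1),
                                  y = .data$log2fc,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log10 mean expression", y = "log2 fold-change",
                  colour = "adj. p < threshold") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Incoming versus outgoing interaction counts per cell type
#'
#' @param inout An [inout_counts()] tibble.
#' @return A ggplot object.
#' @export
plot_inout <- function(inout) {
  ggplot2::ggplot(inout, ggplot2::aes(x = .data$outgoing,
                                      y = .data$incoming,
                                      label = .data$celltype)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "outgoing interactions", y = "incoming interactions") +
    ggplot2::theme_minimal()
}
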