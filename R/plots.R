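# ggplot2 views of the tabular result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of copy counts per genus and family
#'
#' @param object a `copy_count_table` from [copy_counts()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.copy_count_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"genus",
                              names_to = "family", values_to = "copies")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family, y = .data$genus,
                                     fill = .data$copies)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$copies), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "copies",
                  title = "Gene copies per genus") +
    ggplot2::theme_minimal()
}

#' Per-taxon ntRCFV scores with the outlier threshold
#'
#' @param object an `rcfv_profile` from [rcfv_scores()].
#' @param k_sd threshold drawn (default 3).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
autoplot.rcfv_profile <- function(object, k_sd = 3, ...) {
  sc <- flag_heterogeneous(object, k_sd = k_sd)
  ggplot2::ggplot(sc, ggplot2::aes(x = stats::reorder(.data$taxon, .data$ntRCFV),
                                   y = .data$ntRCFV, fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$nRCFV, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$nRCFV + k_sd * object$sd,
                        colour = "firebrick") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ntRCFV",
                  title = "Compositional heterogeneity (dashed: nRCFV; red: flag threshold)") +
    ggplot2::theme_minimal()
}
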