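# ggplot2 views of fitted objects.

#' @export
autoplot.cafw_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace),
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = "Objective trace of the feature-weighted k-medians fit",
                  x = "sweep", y = "objective J")
}

#' @export
autoplot.screening_report <- function(object, ...) {
  df <- dplyr::filter(object$gene_table, .data$survived_s1,
                      is.finite(.data$cv), .data$cv > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mean_weight),
                                   y = log(.data$cv^2),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_abline(slope = object$trend$slope,
                         intercept = object$trend$intercept,
                         linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(title = "Weight-deviation screen: CV trend and selected genes",
                  x = "log10(mean weight across clusters)",
                  y = "log(CV^2)", colour = "selected")
}

#' Heatmap of the cluster x gene weight matrix
#'
#' @param fit a `cafw_fit`.
#' @param genes optional subset of gene ids to show (default: the 50 genes
#'   with the highest weight spread across clusters).
#' @return A ggplot object.
#' @export
plot_weight_heatmap <- function(fit, genes = NULL) {
  df <- tidy(fit)
  if (is.null(genes)) {
    spread <- df |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(spread = max(.data$weight) - min(.data$weight)) |>
      dplyr::arrange(dplyr::desc(.data$spread))
    genes <- head(spread$gene_id, 50)
  }
  df <- dplyr::filter(df, .data$gene_id %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = factor(.data$cluster),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "gene", y = "cluster", fill = "weight") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}
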