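#' Plot a preferential-expression matrix
#'
#' Tile heatmap of Z-scores, genes x cell types. With many genes, restrict
#' via `genes` first.
#'
#' @param object A `pref_expr`.
#' @param genes Optional character vector of genes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pref_expr <- function(object, genes = NULL, ...) {
  df <- tidy(object)
  if (!is.null(genes)) df <- filter(df, .data$gene %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$gene,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z",
                  title = sprintf("Preferential expression — %s", object$tissue)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot PrEDiCT scores per disease and cell type
#'
#' Tile plot of scores with likely associations outlined.
#'
#' @param object A `predict_result`.
#' @param tissue Optional tissue to restrict to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.predict_result <- function(object, tissue = NULL, ...) {
  df <- tidy(object)
  if (!is.null(tissue)) df <- df[df$tissue == tissue, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$disease_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$likely, ], fill = NA, colour = "black",
                       linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::facet_wrap(~tissue, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PrEDiCT") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot false-positive and false-negative rates across FDR thresholds
#'
#' @param curve Output of [error_rates_vs_threshold()].
#' @param fdr_threshold Dashed vertical reference line (default 0.1).
#' @return A ggplot object.
#' @export
plot_error_rates <- function(curve, fdr_threshold = 0.1) {
  long <- tidyr::pivot_longer(curve, c("fpr", "fnr"),
                              names_to = "rate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$rate)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = fdr_threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(fpr = "firebrick", fnr = "darkorange"),
                                 labels = c(fpr = "false positive",
                                            fnr = "false negative")) +
    ggplot2::labs(x = "FDR threshold", y = "rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cell-type match table
#'
#' Tile plot of pairwise Jaccard indices with matched pairs outlined.
#'
#' @param matches Output of [call_matches()].
#' @return A ggplot object.
#' @export
plot_matches <- function(matches) {
  ggplot2::ggplot(matches, ggplot2::aes(x = .data$cell_type_b,
                                        y = .data$cell_type_a,
                                        fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = matches[matches$matched, ], fill = NA,
                       colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "cell type (B)", y = "cell type (A)", fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot susceptibility by cell class
#'
#' @param susc Output of [susceptibility()].
#' @param classes Tibble mapping `cell_type` to `class`.
#' @return A ggplot object.
#' @export
plot_susceptibility <- function(susc, classes) {
  df <- inner_join(susc, classes, by = "cell_type")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$susceptibility)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "susceptibility") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
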