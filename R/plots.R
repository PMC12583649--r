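#' Volcano plot of differential results
#'
#' Works for DIR tables (effect = `delta`, influence difference) and DEG
#' tables (effect = `log2_fc`).  Points are colored by class (`up` red,
#' `down` green, `ns` grey), with the classification thresholds drawn.
#'
#' @param results Tibble from [identify_dirs()] or [identify_degs()].
#' @param effect_cut Vertical threshold lines (defaults to 0.5 for DIR
#'   tables, `log2(1.5)` for DEG tables).
#' @param max_adj_p Horizontal adjusted-p threshold line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, effect_cut = NULL, max_adj_p = 0.05) {
  effect_col <- if ("delta" %in% names(results)) "delta" else "log2_fc"
  if (is.null(effect_cut)) {
    effect_cut <- if (effect_col == "delta") 0.5 else log2(1.5)
  }
  ggplot2::ggplot(results, ggplot2::aes(
    x = .data[[effect_col]], y = -log10(.data$adj_p), color = .data$class
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-effect_cut, effect_cut),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(max_adj_p),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(up = "#c0392b", down = "#1e8449",
                                           ns = "grey60")) +
    ggplot2::labs(
      x = if (effect_col == "delta") "influence difference" else
        "log2 fold change",
      y = "-log10 adjusted p", color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn influence_matrix `autoplot()` draws a regulator-by-sample
#'   influence heatmap (samples grouped by condition when a design is
#'   attached).
#' @param object An `influence_matrix`.
#' @method autoplot influence_matrix
#' @export
autoplot.influence_matrix <- function(object, ...) {
  long <- tidy(object)
  long <- long[!is.na(long$influence), , drop = FALSE]
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sample, y = .data$regulator, fill = .data$influence
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#1e8449", mid = "white",
                                  high = "#c0392b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "influence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if ("condition" %in% names(long)) {
    p <- p + ggplot2::facet_grid(~condition, scales = "free_x",
                                 space = "free_x")
  }
  p
}

#' Dot plot of gene-set over-representation results
#'
#' Gene ratio (overlap / query size) against set name, point size by
#' overlap, color by adjusted p-value.
#'
#' @param enrichment Tibble from [enrich_gene_sets()].
#' @param max_sets Show at most this many sets (by p-value).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, max_sets = 20) {
  top <- head(dplyr::arrange(enrichment, .data$p_value), max_sets)
  top$set_name <- factor(top$set_name, levels = rev(top$set_name))
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$gene_ratio, y = .data$set_name,
    size = .data$overlap, color = .data$adj_p
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "#c0392b", high = "#2c3e50") +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "overlap",
                  color = "adj. p") +
    ggplot2::theme_minimal()
}
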