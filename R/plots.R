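#' Heatmap of the most abundant taxa with CST clustering
#'
#' Samples in dendrogram order on the x-axis, the `top_n` most abundant taxa
#' on the y-axis, square-root relative abundance as fill, annotated by CST.
#'
#' @param ra Relative-abundance tibble.
#' @param clustering A labelled `cst_clustering`.
#' @param top_n Number of taxa shown; default 25.
#' @return A ggplot object.
#' @export
plot_cst_heatmap <- function(ra, clustering, top_n = 25) {
  stopifnot(inherits(clustering, "cst_clustering"))
  taxa <- taxon_names(ra)
  mean_ab <- colMeans(as.matrix(ra[taxa]))
  top <- names(sort(mean_ab, decreasing = TRUE))[seq_len(min(top_n, length(taxa)))]
  ord <- clustering$tree$labels[clustering$tree$order]
  long <- ra[c("sample_id", top)] %>%
    tidyr::pivot_longer(-"sample_id", names_to = "taxon", values_to = "abundance") %>%
    dplyr::left_join(clustering$assignments, by = "sample_id") %>%
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = ord),
                  taxon = factor(.data$taxon, levels = rev(top)))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$taxon,
                                     fill = sqrt(.data$abundance))) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(~ .data$cst, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_viridis_c(name = "sqrt(rel. abundance)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = "sample (dendrogram order)", y = NULL)
}

#' Per-subject CST timeline
#'
#' One row per subject, one tile per sample, coloured by community state
#' type and placed at its gestational age; faceted by study group.
#'
#' @param clustering A labelled `cst_clustering`.
#' @param meta Metadata tibble.
#' @return A ggplot object.
#' @export
plot_cst_timeline <- function(clustering, meta) {
  stopifnot(inherits(clustering, "cst_clustering"))
  df <- dplyr::inner_join(clustering$assignments, meta, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$gestational_age, .data$subject_id,
                                   fill = .data$cst)) +
    ggplot2::geom_tile(width = 1.6, height = 0.8) +
    ggplot2::facet_grid(.data$group ~ ., scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_brewer(palette = "Set1", name = "CST") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::labs(x = "gestational age (weeks)", y = "subject")
}

#' @export
autoplot.cst_clustering <- function(object, ra, ...) {
  plot_cst_heatmap(ra, object, ...)
}

#' @export
autoplot.diversity_comparison <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(.data$group, .data$sdi, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::labs(x = NULL, y = "Shannon Diversity Index")
}

#' Volcano-style summary of the group comparison
#'
#' Signed fold change against -log10 q-value per phylotype, with the
#' significance thresholds drawn.
#'
#' @param diff Result tibble of [run_group_comparison()].
#' @param fdr,fc_threshold Thresholds to draw; defaults 0.1 and 1.5.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(diff, fdr = 0.1, fc_threshold = 1.5) {
  df <- diff[diff$fitted, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$fold_change, -log10(.data$q_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = 3) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::labs(x = "signed fold change", y = "-log10 q-value")
}
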