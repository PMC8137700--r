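#' Plot a projected query over the reference UMAP
#'
#' Reference cells are drawn as points colored by subtype; query cells are
#' overlaid as black points with 2D density contours, the standard way to
#' read where a projected dataset lands on the map.
#'
#' @param atlas A labelled `reference_atlas`.
#' @param result Optional `projection_result` to overlay.
#' @return A ggplot object.
#' @export
plot_projection <- function(atlas, result = NULL) {
  stopifnot(inherits(atlas, "reference_atlas"))
  ref <- tibble::tibble(UMAP1 = atlas$umap_embeddings[, 1],
                        UMAP2 = atlas$umap_embeddings[, 2],
                        subtype = atlas$labels %||% "reference")
  p <- ggplot2::ggplot(ref, ggplot2::aes(.data$UMAP1, .data$UMAP2)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$subtype), size = 0.4,
                        alpha = 0.6) +
    ggplot2::theme_minimal() +
    ggplot2::guides(color = ggplot2::guide_legend(
      override.aes = list(size = 2, alpha = 1)))
  if (!is.null(atlas$subtype_palette)) {
    p <- p + ggplot2::scale_color_manual(values = atlas$subtype_palette)
  }
  if (!is.null(result)) {
    qry <- tibble::tibble(UMAP1 = result$umap_coords[, 1],
                          UMAP2 = result$umap_coords[, 2])
    p <- p +
      ggplot2::geom_point(data = qry, size = 0.3, color = "black") +
      ggplot2::geom_density_2d(data = qry, color = "black", linewidth = 0.3)
  }
  p
}

#' Bar plot of subtype composition per condition
#'
#' @param composition Output of [subtype_composition()].
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(.data$subtype, .data$fraction,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Density plot of one ICA dimension, query vs baseline
#'
#' @param query,baseline `projection_result`s or a `reference_atlas`.
#' @param dimension Component name (e.g. `"ICA25"`).
#' @return A ggplot object.
#' @export
plot_discriminant_density <- function(query, baseline, dimension) {
  df <- dplyr::bind_rows(
    tibble::tibble(value = ica_coords_of(query)[, dimension], side = "query"),
    tibble::tibble(value = ica_coords_of(baseline)[, dimension],
                   side = "baseline"))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, fill = .data$side)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = dimension, y = "density") +
    ggplot2::theme_minimal()
}

#' Heatmap of the marker-consensus profile matrix
#'
#' Uses `pheatmap` when available (Ward-clustered rows and columns, as in
#' the consensus analysis), otherwise falls back to [stats::heatmap()].
#'
#' @param consensus Output of [marker_consensus()].
#' @param ... Passed to the heatmap engine.
#' @return The heatmap object, invisibly.
#' @export
plot_marker_heatmap <- function(consensus, ...) {
  z <- consensus$profile
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    ph <- pheatmap::pheatmap(
      z, cluster_rows = consensus$row_hclust,
      cluster_cols = consensus$col_hclust, silent = TRUE, ...)
    invisible(ph)
  } else {
    stats::heatmap(z, Rowv = stats::as.dendrogram(consensus$row_hclust),
                   Colv = stats::as.dendrogram(consensus$col_hclust), ...)
  }
}
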