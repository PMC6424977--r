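#' Barcode-rank plot with droplet calls
#'
#' @param droplets output of [test_droplets()].
#' @return a ggplot.
#' @export
plot_barcode_ranks <- function(droplets) {
  d <- droplets |>
    dplyr::filter(.data$total > 0) |>
    dplyr::arrange(dplyr::desc(.data$total)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$total, colour = .data$call)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "total UMIs", colour = NULL) +
    ggplot2::theme_classic()
}

#' Embedding coloured by pseudotime (or any per-cell value)
#'
#' @param embedding a `sperm_pca`.
#' @param colour per-cell values (e.g. pseudotime, cluster, complexity).
#' @param dims two components to show.
#' @return a ggplot.
#' @export
plot_embedding <- function(embedding, colour = NULL, dims = c(1, 2)) {
  S <- embedding$scores
  d <- tibble::tibble(x = S[, dims[1]], y = S[, dims[2]])
  if (!is.null(colour)) d$colour <- colour
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = paste0("PC", dims[1]), y = paste0("PC", dims[2])) +
    ggplot2::theme_classic()
  if (is.null(colour)) p + ggplot2::geom_point(size = 0.5)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), size = 0.5) +
    ggplot2::labs(colour = NULL)
}

#' X:A ratio along the trajectory
#'
#' @param xa output of [xa_ratio()].
#' @param pseudotime per-cell pseudotime aligned to `xa`.
#' @return a ggplot showing the X:A and Y:A ratios over pseudotime.
#' @export
plot_xa_trajectory <- function(xa, pseudotime) {
  d <- xa |>
    dplyr::mutate(pseudotime = pseudotime) |>
    tidyr::pivot_longer(c("ratio_auto", "ratio_x", "ratio_y"),
                        names_to = "chromosome", values_to = "ratio")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pseudotime, y = .data$ratio,
                                  colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x) +
    ggplot2::theme_classic()
}

#' Stage-composition tiles per sample
#'
#' @param comp output of [composition()].
#' @return a ggplot of per-sample cluster fractions.
#' @export
plot_composition <- function(comp) {
  long <- attr(comp, "long")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$cluster,
                                     fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Escape-gene temporal heatmap
#'
#' @param heat output of [escape_heatmap_table()].
#' @return a ggplot.
#' @export
plot_escape_heatmap <- function(heat) {
  ggplot2::ggplot(heat, ggplot2::aes(x = .data$stage, y = .data$gene,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z") +
    ggplot2::theme_classic()
}
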