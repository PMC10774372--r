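#' Heatmap of co-localization enrichment scores
#'
#' @param object An `enrichment_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot of log2 enrichment, starred where the
#'   permutation p-value is below 0.05.
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(df, dplyr::rename(
    dplyr::filter(df, .data$type_a != .data$type_b),
    type_a = "type_b", type_b = "type_a"))
  ggplot2::ggplot(df2, ggplot2::aes(.data$type_a, .data$type_b,
                                    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(!is.na(.data$p_value) & .data$p_value < 0.05, "*", "")),
      size = 5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2\nenrichment") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Stacked-bar view of deconvolved state proportions
#'
#' @param object A `deconvolution_result`.
#' @param metadata Optional tibble with `sample` and `compartment` to
#'   facet by compartment.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deconvolution_result <- function(object, metadata = NULL, ...) {
  df <- tidy(object)
  if (!is.null(metadata))
    df <- dplyr::left_join(df, metadata, by = "sample")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$proportion,
                                        fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(metadata) && "compartment" %in% names(df))
    p <- p + ggplot2::facet_wrap(~compartment, scales = "free_x")
  p
}

#' Lineage tree over cluster centroids in PC space
#'
#' @param object A `lineage_set`.
#' @param cells_pc Optional cells x PCs matrix drawn underneath.
#' @param ... Unused.
#' @return A ggplot of the first two dimensions.
#' @export
autoplot.lineage_set <- function(object, cells_pc = NULL, ...) {
  cent <- tibble::as_tibble(object$centroids[, 1:2, drop = FALSE],
                            .name_repair = ~c("d1", "d2")) |>
    dplyr::mutate(cluster = rownames(object$centroids))
  seg <- dplyr::mutate(
    object$mst_edges,
    x = cent$d1[match(.data$from, cent$cluster)],
    y = cent$d2[match(.data$from, cent$cluster)],
    xend = cent$d1[match(.data$to, cent$cluster)],
    yend = cent$d2[match(.data$to, cent$cluster)])
  p <- ggplot2::ggplot()
  if (!is.null(cells_pc))
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(d1 = cells_pc[, 1], d2 = cells_pc[, 2]),
      ggplot2::aes(.data$d1, .data$d2), colour = "grey80", size = 0.3)
  p +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_label(data = cent,
                        ggplot2::aes(.data$d1, .data$d2,
                                     label = .data$cluster)) +
    ggplot2::labs(x = "PC1", y = "PC2")
}

#' Compartment map with nodule regions
#'
#' @param object A `compartment_map`.
#' @param positions Tibble with `cell_id`, `x`, `y` to overlay cells.
#' @param ... Unused.
#' @return A ggplot raster of nodule regions, with cells overlaid when
#'   positions are supplied.
#' @export
autoplot.compartment_map <- function(object, positions = NULL, ...) {
  step <- object$grid_step
  grid_df <- tibble::tibble(
    x = rep((seq_len(nrow(object$regions)) - 0.5) * step,
            ncol(object$regions)),
    y = rep((seq_len(ncol(object$regions)) - 0.5) * step,
            each = nrow(object$regions)),
    nodular = as.vector(object$regions) > 0)
  p <- ggplot2::ggplot(grid_df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$nodular)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95",
                                          `TRUE` = "lightsteelblue")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "nodular")
  if (!is.null(positions)) {
    df <- dplyr::left_join(as.data.frame(positions), object$cells,
                           by = "cell_id")
    p <- p + ggplot2::geom_point(data = df,
                                 ggplot2::aes(colour = .data$compartment),
                                 size = 0.3)
  }
  p
}

#' @importFrom rlang .data
NULL
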