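#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_segment scale_fill_gradient labs theme_minimal stat_function
#' @export
ggplot2::autoplot

#' Plot the fitted mean-variance background model
#'
#' Per-gene log2 variance against log2 mean with the fitted second-order
#' polynomial (clamped at the Poisson floor) overlaid.
#'
#' @param object A `background_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.background_model <- function(object, ...) {
  a <- object$coefficients
  ggplot(object$fit, aes(x = log2(.data$mean), y = log2(.data$variance))) +
    geom_point(alpha = 0.3, size = 0.8) +
    stat_function(fun = function(l) {
      pmax(a[["a0"]] + a[["a1"]] * l + a[["a2"]] * l^2, l)
    }, colour = "firebrick") +
    labs(x = "log2 mean", y = "log2 variance",
         title = "Background noise model") +
    theme_minimal()
}

#' Heatmap of stage-mapping weights
#'
#' Query cells (ordered by their argmax reference cluster) against reference
#' clusters, fill = simplex weight on the 0-1 scale.
#'
#' @param object A `stage_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stage_map <- function(object, ...) {
  d <- tidy.stage_map(object)
  cell_order <- names(sort(object$best))
  d$cell <- factor(d$cell, levels = cell_order)
  ggplot(d, aes(x = .data$ref_cluster, y = .data$cell,
                fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkblue", limits = c(0, 1)) +
    labs(x = "reference cluster", y = "query cell", fill = "weight") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Smoothed pseudo-temporal expression profiles
#'
#' @param object A `trajectory_result`.
#' @param genes Genes to draw (default first 6 smoothed genes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_result <- function(object, genes = NULL, ...) {
  genes <- genes %||% head(rownames(object$smoothed), 6)
  d <- tibble::as_tibble(object$smoothed[genes, , drop = FALSE],
                         rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cell", values_to = "expr")
  d$rank <- object$order$rank[match(d$cell, object$order$cell)]
  ggplot(d, aes(x = .data$rank, y = .data$expr, colour = .data$gene)) +
    geom_line() +
    labs(x = "pseudotime rank", y = "smoothed log2 expression") +
    theme_minimal()
}

#' Lineage graph with link scores and significance
#'
#' Clusters are placed on a circle; edge width encodes the link score and
#' only significant links (p < pthr) are drawn solid.
#'
#' @param object A `lineage_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lineage_graph <- function(object, ...) {
  v <- object$vertices
  theta <- seq(0, 2 * pi, length.out = nrow(v) + 1)[seq_len(nrow(v))]
  v$x <- cos(theta); v$y <- sin(theta)
  e <- object$edges
  e$x <- v$x[match(e$from, v$cluster)]
  e$y <- v$y[match(e$from, v$cluster)]
  e$xend <- v$x[match(e$to, v$cluster)]
  e$yend <- v$y[match(e$to, v$cluster)]
  ggplot() +
    geom_segment(data = e,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, linewidth = .data$score,
                     linetype = !.data$significant),
                 colour = "grey40") +
    geom_point(data = v, aes(x = .data$x, y = .data$y,
                             colour = .data$median_entropy, size = .data$n_cells)) +
    ggplot2::geom_text(data = v, aes(x = 1.1 * .data$x, y = 1.1 * .data$y,
                                     label = .data$cluster)) +
    ggplot2::scale_linetype_manual(values = c("solid", "dotted"),
                                   guide = "none") +
    labs(colour = "median entropy", size = "cells") +
    ggplot2::theme_void()
}
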