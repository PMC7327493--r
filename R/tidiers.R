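#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a background noise model into its coefficients
#' @param x A `background_model`.
#' @param ... Unused.
#' @return Tibble with term/estimate columns.
#' @export
tidy.background_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.background_model
#' @export
glance.background_model <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$fit), r_squared = x$r_squared,
                 log2_mean_min = x$domain[1], log2_mean_max = x$domain[2])
}

#' Tidy a cluster model into one row per cell
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return Tibble with cell, cluster, is_outlier, is_medoid.
#' @export
tidy.cluster_model <- function(x, ...) {
  tibble::tibble(cell = names(x$labels), cluster = unname(x$labels),
                 is_outlier = unname(x$outlier),
                 is_medoid = names(x$labels) %in% x$medoids)
}

#' @rdname tidy.cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_cells = length(x$labels),
                 n_outliers = sum(x$outlier),
                 within_dispersion = x$dispersion_path$within[x$k])
}

#' Tidy a stage map into one row per (cell, reference cluster)
#' @param x A `stage_map`.
#' @param ... Unused.
#' @return Long tibble with cell, ref_cluster, weight.
#' @export
tidy.stage_map <- function(x, ...) {
  tibble::as_tibble(x$weights, rownames = "cell") |>
    tidyr::pivot_longer(-"cell", names_to = "ref_cluster",
                        values_to = "weight")
}

#' @rdname tidy.stage_map
#' @export
glance.stage_map <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$weights), n_ref_clusters = ncol(x$weights),
                 n_flagged = sum(x$flagged),
                 mean_residual = mean(x$residual))
}

#' Tidy a lineage graph into its edge list
#' @param x A `lineage_graph`.
#' @param ... Unused.
#' @return Edge tibble with -log10 p added.
#' @export
tidy.lineage_graph <- function(x, ...) {
  dplyr::mutate(x$edges, neg_log10_p = -log10(pmax(.data$pval, 1e-300)))
}

#' Tidy a trajectory into its cell ordering
#' @param x A `trajectory_result`.
#' @param ... Unused.
#' @return The order tibble (cell, cluster, chain_position, coordinate, rank).
#' @export
tidy.trajectory_result <- function(x, ...) x$order

#' Tidy SOM modules into one row per gene
#' @param x A `som_result`.
#' @param ... Unused.
#' @return Tibble with gene, node, module.
#' @export
tidy.som_result <- function(x, ...) x$modules

#' Tidy a GRN into its ranked edge list
#' @param x A `grn_result`.
#' @param ... Unused.
#' @return Tibble with regulator, target, weight, rank.
#' @export
tidy.grn_result <- function(x, ...) x$edges

#' Tidy GRN modules into one row per gene
#' @param x A `grn_modules`.
#' @param ... Unused.
#' @return Tibble with gene, module.
#' @export
tidy.grn_modules <- function(x, ...) x$membership
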