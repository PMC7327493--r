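#' Configuration for gene regulatory network inference
#'
#' @param min_transcripts,min_cells Expression filter: a gene enters the
#'   inference iff it has more than `min_transcripts` transcripts in at least
#'   `min_cells` cells (defaults 4 and 2; the single-cell adult profile uses
#'   5 and 1, see [filter_grn_genes()]).
#' @param n_trees Trees per random forest (default 1000).
#' @param mtry Candidate features per split; default `sqrt` of the predictor
#'   count.
#' @param top_edges Number of top-ranked edges retained (default 1000).
#' @param seed Seed; edge weights are deterministic given it.
#' @return List of class `grn_config`.
#' @export
grn_config <- function(min_transcripts = 4, min_cells = 2, n_trees = 1000,
                       mtry = NULL, top_edges = 1000, seed = 1) {
  if (top_edges < 1) stop_config("top_edges must be >= 1")
  if (n_trees < 1) stop_config("n_trees must be >= 1")
  structure(list(min_transcripts = min_transcripts, min_cells = min_cells,
                 n_trees = as.integer(n_trees), mtry = mtry,
                 top_edges = as.integer(top_edges), seed = as.integer(seed)),
            class = "grn_config")
}

#' Expression filter for GRN genes
#'
#' Keeps a gene iff its (normalized) count strictly exceeds
#' `min_transcripts` in at least `min_cells` cells.
#'
#' @param x `transcript_counts` or matrix.
#' @param min_transcripts,min_cells Filter thresholds.
#' @return Character vector of retained genes (hard error when empty).
#' @export
filter_grn_genes <- function(x, min_transcripts = 4, min_cells = 2) {
  counts <- as_count_matrix(x)
  keep <- rowSums(counts > min_transcripts) >= min_cells
  if (!any(keep)) stop_data("no genes pass the GRN expression filter")
  rownames(counts)[keep]
}

#' Random-forest gene regulatory network edge ranking
#'
#' For each target gene, a random-forest regression of its standardized
#' expression on all other (candidate regulator) genes is fitted; the edge
#' weight regulator -> target is the regulator's total variance-reduction
#' importance, normalized per target by the sum over all regulators. Edges
#' are pooled across targets, ranked by weight (ties broken
#' lexicographically by regulator then target) and truncated to
#' `top_edges`. Cells are ordered canonically by id before fitting, so the
#' ranking is invariant to input cell order at a fixed seed.
#'
#' @param x `transcript_counts` or matrix, restricted to the filtered genes
#'   (see [filter_grn_genes()]); needs >= 3 genes and >= 10 cells.
#' @param config A [grn_config()].
#' @param genes Optional gene subset (default all rows).
#' @return Object of class `grn_result`: `edges` tibble (regulator, target,
#'   weight, rank), `genes`, `config`.
#' @export
infer_grn <- function(x, config = grn_config(), genes = NULL) {
  counts <- as_count_matrix(x)
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (nrow(counts) < 3) stop_data("GRN inference needs >= 3 genes")
  if (ncol(counts) < 10) stop_data("GRN inference needs >= 10 cells")
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  sdv <- apply(counts, 1, stats::sd)
  z <- counts
  z[sdv > 0, ] <- t(scale(t(counts[sdv > 0, , drop = FALSE])))
  gene_ids <- rownames(counts)

  edges <- purrr::map_dfr(seq_along(gene_ids), function(ti) {
    tgt <- gene_ids[ti]
    if (sdv[ti] == 0) return(NULL) # constant target contributes no edges
    predictors <- gene_ids[-ti]
    X <- as.data.frame(t(z[predictors, , drop = FALSE]))
    names(X) <- predictors
    p <- length(predictors)
    fit <- ranger::ranger(
      x = X, y = as.numeric(z[ti, ]),
      num.trees = config$n_trees,
      mtry = config$mtry %||% max(1L, floor(sqrt(p))),
      importance = "impurity",
      seed = config$seed + ti,
      num.threads = 1
    )
    imp <- pmax(fit$variable.importance, 0)
    total <- sum(imp)
    if (total == 0) return(NULL)
    tibble::tibble(regulator = predictors, target = tgt,
                   weight = unname(imp) / total)
  })
  edges <- dplyr::arrange(edges, dplyr::desc(.data$weight),
                          .data$regulator, .data$target)
  edges <- head(edges, config$top_edges)
  edges$rank <- seq_len(nrow(edges))
  structure(list(edges = edges, genes = gene_ids, config = config),
            class = "grn_result")
}

#' @export
print.grn_result <- function(x, ...) {
  cat(sprintf("<grn_result> %d ranked edges over %d genes\n",
              nrow(x$edges), length(x$genes)))
  invisible(x)
}

#' Network modules of a ranked edge list
#'
#' Connected components of the undirected graph over the top-ranked edges.
#' When an expression matrix is supplied, each module also gets a per-cell
#' aggregated-expression score (mean of the member genes' z-scores), suitable
#' for overlay on an external embedding.
#'
#' @param grn A `grn_result` or an edge tibble with regulator/target columns.
#' @param x Optional `transcript_counts`/matrix for module scores.
#' @return Object of class `grn_modules`: `membership` tibble (gene, module),
#'   `n_modules`, and optionally `scores` (modules x cells matrix).
#' @export
extract_modules <- function(grn, x = NULL) {
  edges <- if (inherits(grn, "grn_result")) grn$edges else tibble::as_tibble(grn)
  if (nrow(edges) == 0) stop_data("empty edge list")
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator", "target")], directed = FALSE)
  comp <- igraph::components(g)
  membership <- tibble::tibble(gene = names(comp$membership),
                               module = as.integer(comp$membership))
  membership <- dplyr::arrange(membership, .data$module, .data$gene)
  scores <- NULL
  if (!is.null(x)) {
    counts <- as_count_matrix(x)
    genes <- intersect(membership$gene, rownames(counts))
    zc <- t(scale(t(counts[genes, , drop = FALSE])))
    zc[is.na(zc)] <- 0
    scores <- do.call(rbind, lapply(seq_len(as.integer(comp$no)), function(m) {
      members <- intersect(membership$gene[membership$module == m], genes)
      colMeans(zc[members, , drop = FALSE])
    }))
    rownames(scores) <- paste0("module", seq_len(comp$no))
  }
  structure(list(membership = membership, n_modules = as.integer(comp$no),
                 scores = scores),
            class = "grn_modules")
}
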