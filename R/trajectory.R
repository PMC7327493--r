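#' Transcriptome entropy of a cell profile
#'
#' Shannon entropy (nats) of the normalized expression fractions:
#' `H = -sum p_g log p_g` over expressed genes, with `p_g = x_g / sum(x)`.
#' Bounded by `log` of the number of expressed genes; differentiating cells
#' typically lose entropy as their transcriptome specializes.
#'
#' @param profile Non-negative expression vector with positive total.
#' @return Entropy in nats.
#' @export
compute_entropy <- function(profile) {
  if (any(profile < 0)) stop_data("negative expression values")
  total <- sum(profile)
  if (total <= 0) stop_data("profile has zero total")
  p <- profile[profile > 0] / total
  -sum(p * log(p))
}

#' Infer lineage links between clusters by medoid-segment projection
#'
#' Each cell is projected onto the line segments joining its cluster medoid
#' to every other cluster medoid (in log-transformed feature space) and
#' assigned to the link with the largest positive projection. The link score
#' of an edge is the fraction of the two flanking clusters' cells assigned to
#' it; its p-value is the binomial tail of the observed link occupancy
#' against uniform occupancy (a cell falls on one of a cluster's K - 1
#' candidate links, or on none, with probability 1/K each, K the number of
#' clusters). Edges with p below `pthr` are significant; clusters smaller
#' than `cthr` are excluded from the graph.
#'
#' @param model A `cluster_model` (outliers are kept as ordinary members).
#' @param x The `transcript_counts` the model was fitted on.
#' @param cthr Minimum cluster size (default 15).
#' @param pthr Link significance threshold (default 0.01).
#' @param scthr Minimum link score for an edge to be marked strong
#'   (default 0.6; presentation only, does not affect p-values).
#' @return Object of class `lineage_graph`: `edges` tibble (from, to,
#'   cells_on_link, score, pval, significant, strong), `vertices` tibble
#'   (cluster, n_cells, median_entropy), `assignment` (per-cell link), and
#'   parameters.
#' @export
infer_lineage_links <- function(model, x, cthr = 15, pthr = 0.01,
                                scthr = 0.6) {
  counts <- as_count_matrix(x)
  features <- model$features %||%
    (if (inherits(x, "transcript_counts")) x$feature_genes else rownames(counts))
  pc <- if (inherits(x, "transcript_counts")) x$pseudocount else 0.1
  lp <- log_profile(counts[features, names(model$labels), drop = FALSE], pc)

  sizes <- table(model$labels)
  clusters <- as.integer(names(sizes)[sizes >= cthr])
  if (length(clusters) < 2) {
    stop_data("need >= 2 clusters of size >= cthr = %d", cthr)
  }
  K <- length(clusters)
  med <- lp[, model$medoids[as.character(clusters)], drop = FALSE]
  colnames(med) <- as.character(clusters)

  cells <- names(model$labels)[model$labels %in% clusters]
  assign_to <- setNames(rep(NA_integer_, length(cells)), cells)
  for (cell in cells) {
    own <- model$labels[[cell]]
    mc <- med[, as.character(own)]
    best_t <- 0
    best_cl <- NA_integer_
    for (other in setdiff(clusters, own)) {
      v <- med[, as.character(other)] - mc
      vv <- sum(v^2)
      if (vv == 0) {
        warn(sprintf("coincident medoids for clusters %d and %d; link skipped",
                     own, other))
        next
      }
      t_proj <- sum((lp[, cell] - mc) * v) / vv
      if (t_proj > best_t) {
        best_t <- t_proj
        best_cl <- other
      }
    }
    assign_to[cell] <- best_cl
  }

  pairs <- utils::combn(clusters, 2)
  edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    c1 <- pairs[1, i]; c2 <- pairs[2, i]
    cells1 <- cells[model$labels[cells] == c1]
    cells2 <- cells[model$labels[cells] == c2]
    n12 <- sum(assign_to[cells1] == c2, na.rm = TRUE)
    n21 <- sum(assign_to[cells2] == c1, na.rm = TRUE)
    # one binomial tail per flanking cluster against the uniform null 1/K;
    # the edge carries the stronger (smaller) of the two
    p1 <- pbinom(n12 - 1, length(cells1), 1 / K, lower.tail = FALSE)
    p2 <- pbinom(n21 - 1, length(cells2), 1 / K, lower.tail = FALSE)
    score <- (n12 + n21) / (length(cells1) + length(cells2))
    tibble::tibble(from = c1, to = c2, cells_on_link = n12 + n21,
                   score = score, pval = min(p1, p2))
  })
  edges$significant <- edges$pval < pthr
  edges$strong <- edges$score > scthr

  entropy <- vapply(cells, function(cell) {
    compute_entropy(counts[, cell])
  }, numeric(1))
  vertices <- tibble::tibble(
    cluster = clusters,
    n_cells = as.integer(sizes[as.character(clusters)]),
    median_entropy = vapply(clusters, function(cl) {
      median(entropy[model$labels[cells] == cl])
    }, numeric(1))
  )
  structure(list(edges = edges, vertices = vertices,
                 assignment = tibble::tibble(cell = cells,
                                             cluster = model$labels[cells],
                                             link_to = assign_to),
                 params = list(cthr = cthr, pthr = pthr, scthr = scthr)),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("<lineage_graph> %d clusters, %d links (%d significant)\n",
              nrow(x$vertices), nrow(x$edges), sum(x$edges$significant)))
  invisible(x)
}

#' Pseudo-temporal ordering along a cluster chain
#'
#' Orders the cells of a user-specified cluster chain by (1) the chain
#' position of their own cluster and (2) their projection coordinate onto
#' the chain direction through that cluster's medoid (the segment from the
#' previous to the next chain medoid; ties broken by cell index). Per-gene
#' pseudo-temporal expression profiles are derived by a local quadratic
#' regression (tricube weights, `stats::loess`) of log-transformed expression
#' across the ordered cells. Reversing the chain reverses the order exactly.
#'
#' @param x `transcript_counts`.
#' @param chain Ordered cluster ids (non-empty; all present in `model`).
#' @param model A `cluster_model`.
#' @param genes Genes to smooth (default the feature set).
#' @param span loess span (default 0.75).
#' @return Object of class `trajectory_result`: `order` tibble (cell,
#'   cluster, chain_position, coordinate, rank), `smoothed` genes x ordered
#'   cells matrix, `chain`, `span`.
#' @export
pseudotime_order <- function(x, chain, model, genes = NULL, span = 0.75) {
  if (length(chain) == 0) stop_data("empty cluster chain")
  counts <- as_count_matrix(x)
  features <- model$features %||%
    (if (inherits(x, "transcript_counts")) x$feature_genes else rownames(counts))
  genes <- genes %||% features
  pc <- if (inherits(x, "transcript_counts")) x$pseudocount else 0.1
  lp <- log_profile(counts[features, names(model$labels), drop = FALSE], pc)
  if (!all(chain %in% model$labels)) {
    stop_data("chain contains clusters absent from the model")
  }
  med <- lp[, model$medoids[as.character(chain)], drop = FALSE]

  ord <- purrr::map_dfr(seq_along(chain), function(pos) {
    cl <- chain[pos]
    cells <- names(model$labels)[model$labels == cl]
    # chain direction through this cluster: previous medoid -> next medoid
    prev <- if (pos > 1) med[, pos - 1] else med[, pos]
    nxt <- if (pos < length(chain)) med[, pos + 1] else med[, pos]
    v <- nxt - prev
    coord <- if (sum(v^2) == 0) rep(0, length(cells)) else {
      as.numeric(crossprod(lp[, cells, drop = FALSE] - med[, pos], v)) /
        sum(v^2)
    }
    tibble::tibble(cell = cells, cluster = cl, chain_position = pos,
                   coordinate = coord)
  })
  ord <- ord[order(ord$chain_position, ord$coordinate, match(ord$cell, names(model$labels))), ]
  ord$rank <- seq_len(nrow(ord))

  ranks <- seq_len(nrow(ord))
  smoothed <- t(vapply(genes, function(g) {
    y <- log_profile(counts[g, ord$cell], pc)
    if (max(y) - min(y) < 1e-12) return(as.numeric(y))
    fit <- loess(y ~ ranks, span = span, degree = 2,
                 family = "gaussian")
    predict(fit, ranks)
  }, numeric(nrow(ord))))
  rownames(smoothed) <- genes
  colnames(smoothed) <- ord$cell
  structure(list(order = tibble::as_tibble(ord), smoothed = smoothed,
                 chain = chain, span = span),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %d cells along %d clusters, %d smoothed genes\n",
              nrow(x$order), length(x$chain), nrow(x$smoothed)))
  invisible(x)
}

# 1-D batch self-organizing map over gene profiles. Deterministic given the
# seed (seeded prototype initialization; batch updates are deterministic).
som_1d <- function(z, n_nodes, epochs, seed) {
  n_genes <- nrow(z)
  withr::with_seed(seed, {
    init <- z[sample(n_genes, n_nodes, replace = n_genes < n_nodes), ,
              drop = FALSE]
  })
  proto <- init
  radius_path <- seq(n_nodes / 3, 0.5, length.out = epochs)
  node_pos <- seq_len(n_nodes)
  for (e in seq_len(epochs)) {
    d2 <- outer(rowSums(z^2), rowSums(proto^2), `+`) - 2 * z %*% t(proto)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-outer(node_pos, node_pos[bmu], `-`)^2 / (2 * radius_path[e]^2))
    wsum <- rowSums(h)
    upd <- (h %*% z) / pmax(wsum, .Machine$double.eps)
    moved <- wsum > 0
    proto[moved, ] <- upd[moved, ]
  }
  d2 <- outer(rowSums(z^2), rowSums(proto^2), `+`) - 2 * z %*% t(proto)
  list(prototypes = proto, bmu = max.col(-d2, ties.method = "first"))
}

#' Self-organizing-map modules of pseudo-temporal gene profiles
#'
#' Per-gene z-score transforms the smoothed pseudo-temporal profiles, trains
#' a one-dimensional SOM over the gene profiles, and merges adjacent occupied
#' nodes whose prototypes correlate above `merge_cor` into modules of
#' co-regulated genes. Genes inherit the module of their best-matching node.
#'
#' @param x A `trajectory_result` or a genes x ordered-cells profile matrix.
#' @param n_nodes Number of SOM nodes (default 50, capped at the gene count).
#' @param merge_cor Prototype correlation above which adjacent nodes merge
#'   (default 0.85); module count is non-increasing as this decreases.
#' @param epochs Batch training epochs (default 200).
#' @param seed Seed for the prototype initialization.
#' @return Object of class `som_result`: `modules` tibble (gene, node,
#'   module), `prototypes`, `n_modules`, parameters.
#' @export
som_modules <- function(x, n_nodes = 50, merge_cor = 0.85, epochs = 200,
                        seed = 1) {
  profiles <- if (inherits(x, "trajectory_result")) x$smoothed else x
  sdv <- apply(profiles, 1, stats::sd)
  if (all(sdv == 0)) stop_data("all gene profiles are constant")
  keep <- sdv > 0
  z <- t(scale(t(profiles[keep, , drop = FALSE])))
  genes <- rownames(profiles)[keep]
  if (length(genes) == 1) {
    out <- tibble::tibble(gene = genes, node = 1L, module = 1L)
    return(structure(list(modules = out, prototypes = z, n_modules = 1L,
                          params = list(n_nodes = 1L, merge_cor = merge_cor,
                                        epochs = epochs, seed = seed)),
                     class = "som_result"))
  }
  n_nodes <- max(2L, min(n_nodes, length(genes)))
  som <- som_1d(z, n_nodes, epochs, seed)

  occupied <- sort(unique(som$bmu))
  module_of_node <- setNames(integer(length(occupied)), occupied)
  module_of_node[1] <- 1L
  if (length(occupied) > 1) {
    for (i in 2:length(occupied)) {
      r <- suppressWarnings(cor(som$prototypes[occupied[i - 1], ],
                                som$prototypes[occupied[i], ]))
      module_of_node[i] <- if (!is.na(r) && r > merge_cor) {
        module_of_node[i - 1]
      } else {
        module_of_node[i - 1] + 1L
      }
    }
  }
  out <- tibble::tibble(
    gene = genes, node = som$bmu,
    module = unname(module_of_node[as.character(som$bmu)])
  )
  structure(list(modules = out, prototypes = som$prototypes,
                 n_modules = max(out$module),
                 params = list(n_nodes = n_nodes, merge_cor = merge_cor,
                               epochs = epochs, seed = seed)),
            class = "som_result")
}

#' @export
print.som_result <- function(x, ...) {
  cat(sprintf("<som_result> %d genes in %d modules\n",
              nrow(x$modules), x$n_modules))
  invisible(x)
}
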