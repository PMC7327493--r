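#' Shared feature genes between two datasets
#'
#' The intersection of the feature genes of the two stages is the gene space
#' in which query cells are projected onto reference medoids.
#'
#' @param features_a,features_b Non-empty feature gene sets.
#' @param min_genes Minimum intersection size (default 10).
#' @return Sorted character vector of shared genes.
#' @export
shared_features <- function(features_a, features_b, min_genes = 10) {
  if (length(features_a) == 0 || length(features_b) == 0) {
    stop_data("feature sets must be non-empty")
  }
  shared <- sort(intersect(features_a, features_b))
  if (length(shared) == 0) stop_data("feature sets are disjoint")
  if (length(shared) < min_genes) {
    stop_data("only %d shared feature genes (need >= %d)",
              length(shared), min_genes)
  }
  shared
}

# Simplex-constrained least squares:
#   minimize ||x - M w||^2  s.t.  sum(w) = 1, w >= 0
# Active-set method in the Lawson-Hanson style adapted to the equality
# constraint: the passive-set subproblem is the KKT linear system of the
# equality-constrained LS; indices entering/leaving are chosen
# deterministically (first index on ties). A tiny ridge is added only if the
# KKT system is numerically singular (duplicate medoids), which makes the
# tie-break deterministic and documented.
solve_simplex_ls <- function(M, x, tol = 1e-10, max_iter = NULL) {
  k <- ncol(M)
  if (k == 1) {
    w <- 1
    return(list(weights = w, residual = sum((x - M[, 1])^2)))
  }
  D <- crossprod(M)
  dv <- crossprod(M, x)[, 1]
  scale <- max(1, max(abs(D)))
  max_iter <- max_iter %||% (10L * k)

  solve_eqp <- function(P) {
    np <- length(P)
    A <- rbind(cbind(2 * D[P, P, drop = FALSE], rep(1, np)),
               c(rep(1, np), 0))
    rhs <- c(2 * dv[P], 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      A[seq_len(np), seq_len(np)] <- A[seq_len(np), seq_len(np)] +
        diag(1e-10 * scale, np)
      solve(A, rhs)
    })
    # the system stores the equality multiplier with opposite sign to the
    # Lagrangian convention g_i = lambda on the passive set
    list(z = sol[seq_len(np)], lambda = -sol[np + 1])
  }

  # start from the single best medoid (feasible vertex)
  start <- which.min(colSums((M - matrix(x, nrow(M), k))^2))
  P <- start
  w <- rep(0, k)
  w[start] <- 1
  lambda <- NA_real_

  for (outer in seq_len(max_iter)) {
    repeat {
      sol <- solve_eqp(P)
      if (all(sol$z >= -tol)) {
        w[] <- 0
        w[P] <- pmax(sol$z, 0)
        w <- w / sum(w)
        lambda <- sol$lambda
        break
      }
      # step towards z until the first passive weight hits zero
      neg <- which(sol$z < -tol)
      alpha <- min(w[P][neg] / (w[P][neg] - sol$z[neg]))
      w[P] <- w[P] + alpha * (sol$z - w[P])
      drop_idx <- P[w[P] <= tol]
      w[drop_idx] <- 0
      P <- setdiff(P, drop_idx[1]) # drop one blocking index (deterministic)
      if (length(P) == 0) {
        P <- start
        w[] <- 0
        w[start] <- 1
      }
    }
    g <- 2 * (D %*% w - dv)[, 1]
    active <- setdiff(seq_len(k), P)
    viol <- lambda - g[active]
    if (length(active) == 0 || max(viol) <= 1e-9 * scale) break
    P <- sort(c(P, active[which.max(viol)]))
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  list(weights = w, residual = sum((x - M %*% w)^2))
}

#' Project a query cell onto reference cluster medoids
#'
#' Finds the simplex weights expressing a query cell's profile as the closest
#' convex combination of reference cluster medoids:
#' `w* = argmin ||x - M w||^2` subject to `w >= 0` and `sum(w) = 1`.
#' This quadratic program is solved with a deterministic active-set method;
#' the returned weights satisfy the simplex constraints to machine tolerance
#' and the KKT optimality conditions.
#'
#' @param x Query profile over the shared feature genes (finite, length =
#'   `nrow(M)`).
#' @param M Medoid matrix: shared feature genes x reference clusters.
#' @return List with `weights` (named by reference cluster) and `residual`
#'   (`||x - M w*||^2`).
#' @export
project_cell <- function(x, M) {
  if (!is.matrix(M) || ncol(M) < 1) stop_data("M must have >= 1 medoid column")
  if (length(x) != nrow(M)) stop_data("profile/medoid dimension mismatch")
  if (!all(is.finite(x)) || !all(is.finite(M))) {
    stop_data("non-finite entries in projection input")
  }
  sol <- solve_simplex_ls(M, as.numeric(x))
  names(sol$weights) <- colnames(M)
  sol
}

#' Medoid expression matrix of a clustered dataset
#'
#' @param x The `transcript_counts` the model was fitted on.
#' @param model A `cluster_model`.
#' @param features Genes (rows) of the medoid matrix.
#' @param min_cluster_size Clusters smaller than this are dropped
#'   (default 1 keeps all).
#' @return Matrix features x clusters of the medoid cells' normalized
#'   expression.
#' @export
medoid_matrix <- function(x, model, features = NULL, min_cluster_size = 1) {
  counts <- as_count_matrix(x)
  features <- features %||%
    (if (inherits(x, "transcript_counts")) x$feature_genes else rownames(counts))
  sizes <- table(model$labels)
  keep <- names(sizes)[sizes >= min_cluster_size]
  med <- model$medoids[keep]
  m <- counts[features, med, drop = FALSE]
  colnames(m) <- keep
  m
}

#' Map every cell of a query dataset onto reference cluster medoids
#'
#' Row-wise [project_cell()] over all query cells, in the shared feature-gene
#' space. Cells with zero expression on the shared features get a uniform
#' weight row and are flagged.
#'
#' @param query `transcript_counts` of the query stage.
#' @param reference `transcript_counts` of the reference stage.
#' @param ref_model `cluster_model` fitted on the reference.
#' @param features Shared feature genes (default
#'   `shared_features(query, reference)` feature sets).
#' @return Object of class `stage_map`: `weights` (query cells x reference
#'   clusters), `residual`, `flagged` (zero-expression cells), `best`
#'   (argmax reference cluster per cell), `features`.
#' @export
map_dataset <- function(query, reference, ref_model, features = NULL) {
  features <- features %||%
    shared_features(query$feature_genes, reference$feature_genes)
  M <- medoid_matrix(reference, ref_model, features = features)
  q <- as_count_matrix(query)[features, , drop = FALSE]
  n <- ncol(q)
  k <- ncol(M)
  W <- matrix(NA_real_, n, k, dimnames = list(colnames(q), colnames(M)))
  resid <- setNames(numeric(n), colnames(q))
  flagged <- setNames(logical(n), colnames(q))
  for (j in seq_len(n)) {
    if (sum(q[, j]) == 0) {
      W[j, ] <- 1 / k
      resid[j] <- sum((M %*% rep(1 / k, k))^2)
      flagged[j] <- TRUE
    } else {
      sol <- project_cell(q[, j], M)
      W[j, ] <- sol$weights
      resid[j] <- sol$residual
    }
  }
  structure(list(
    weights = W, residual = resid, flagged = flagged,
    best = setNames(colnames(M)[max.col(W, ties.method = "first")],
                    rownames(W)),
    features = features
  ), class = "stage_map")
}

#' @export
print.stage_map <- function(x, ...) {
  cat(sprintf("<stage_map> %d query cells x %d reference clusters (%d flagged)\n",
              nrow(x$weights), ncol(x$weights), sum(x$flagged)))
  invisible(x)
}

#' KKT optimality residuals of a projection
#'
#' For the simplex-constrained least-squares solution, optimality requires
#' the gradient components of all active (positive-weight) medoids to equal a
#' common multiplier and those of zero-weight medoids to be no smaller.
#' Returns the worst violations; used by the package's own tests.
#'
#' @param x Query profile.
#' @param M Medoid matrix.
#' @param w Weight vector.
#' @return List with `stationarity` (max spread of active gradients) and
#'   `dual_feasibility` (max of multiplier minus inactive gradients).
#' @export
kkt_residuals <- function(x, M, w) {
  g <- as.numeric(2 * (crossprod(M) %*% w - crossprod(M, x)))
  act <- w > 1e-8
  lambda <- mean(g[act])
  list(stationarity = if (any(act)) max(abs(g[act] - lambda)) else 0,
       dual_feasibility = if (all(act)) 0 else max(lambda - g[!act]))
}
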