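#' Fit the background transcript-count noise model
#'
#' Across genes, fits the second-order polynomial
#' `log2(var) = a0 + a1 * log2(mean) + a2 * log2(mean)^2`
#' of the per-gene variance against the per-gene mean of normalized
#' transcript counts. The fitted variance is clamped below at the mean
#' (Poisson floor), so the predicted distribution is never underdispersed.
#' This mean-variance relation parameterizes the per-gene negative binomial
#' distributions used for outlier detection and differential testing.
#'
#' @param x `transcript_counts` or genes x cells matrix.
#' @param features Genes used for the fit (default the feature set, or all
#'   rows for a bare matrix). Genes with zero mean or zero variance are
#'   excluded from the fit.
#' @return Object of class `background_model`: coefficients `a0, a1, a2`,
#'   fit domain (range of log2 means), and the per-gene fit table.
#' @export
fit_background_model <- function(x, features = NULL) {
  counts <- as_count_matrix(x)
  features <- features %||%
    (if (inherits(x, "transcript_counts")) x$feature_genes else rownames(counts))
  m <- rowMeans(counts[features, , drop = FALSE])
  v <- apply(counts[features, , drop = FALSE], 1, var)
  keep <- m > 0 & v > 0
  if (length(unique(m[keep])) < 3) {
    stop_data("need at least 3 distinct positive gene means to fit the noise model")
  }
  if (sum(keep) < 50) {
    warn("fewer than 50 genes available for the background fit")
  }
  lm_fit <- lm(log2(v[keep]) ~ log2(m[keep]) + I(log2(m[keep])^2))
  structure(list(
    coefficients = setNames(coef(lm_fit), c("a0", "a1", "a2")),
    domain = range(log2(m[keep])),
    fit = tibble::tibble(gene = names(m)[keep], mean = m[keep],
                         variance = v[keep]),
    r_squared = summary(lm_fit)$r.squared
  ), class = "background_model")
}

#' Predicted background variance at a given mean
#'
#' Evaluates the fitted polynomial and applies the Poisson floor
#' (variance >= mean).
#'
#' @param model A `background_model`.
#' @param m Mean expression values (> 0).
#' @return Predicted variances, same length as `m`.
#' @export
predict_background_variance <- function(model, m) {
  stopifnot(inherits(model, "background_model"))
  a <- model$coefficients
  lm2 <- log2(pmax(m, .Machine$double.eps))
  pmax(2^(a[["a0"]] + a[["a1"]] * lm2 + a[["a2"]] * lm2^2), m)
}

# NB size parameter from mean and background variance; clamped so the
# distribution degenerates towards Poisson when variance ~ mean
nb_size_from_model <- function(model, mu) {
  v <- predict_background_variance(model, mu)
  pmin(mu^2 / pmax(v - mu, mu / 1e6), 1e8)
}

# 1 - Pearson correlation distance between cells on log-transformed
# feature-gene profiles
correlation_distance <- function(x, features = NULL, pseudocount = 0.1,
                                 method = c("pearson", "spearman")) {
  counts <- as_count_matrix(x)
  method <- match.arg(method)
  features <- features %||%
    (if (inherits(x, "transcript_counts")) x$feature_genes else rownames(counts))
  lp <- log_profile(counts[features, , drop = FALSE], pseudocount)
  d <- 1 - suppressWarnings(cor(lp, method = method))
  d[is.na(d)] <- 0
  d
}

# medoid of each cluster: member minimizing total distance to members,
# lowest cell index on ties
compute_medoids <- function(d, labels, exclude = character(0)) {
  cells <- rownames(d)
  vapply(as.character(sort(unique(labels))), function(cl) {
    members <- cells[labels == cl]
    eligible <- setdiff(members, exclude)
    if (length(eligible) == 0) eligible <- members
    tot <- colSums(d[members, eligible, drop = FALSE])
    eligible[which.min(tot)]
  }, character(1))
}

#' Cluster cells by k-medoids on a correlation distance
#'
#' Partitions cells with k-medoids (PAM) on the distance
#' `1 - cor(log2(x + pseudocount))` over feature genes. The number of
#' clusters is chosen by within-cluster dispersion saturation: scanning
#' k = 1..`k_max`, the smallest k is selected at which the dispersion
#' decrease `D(k) = W(k) - W(k+1)` has saturated — either the relative
#' decrease `D(k)/W(k)` falls below `saturation_tol`, or `D(k)` collapses to
#' less than half the previous step's decrease (the elbow: past the true
#' cluster number, PAM only carves noise and the decreases flatten onto a
#' roughly constant floor, so the first sharp collapse marks saturation).
#'
#' @param x `transcript_counts` (or matrix).
#' @param k_max Largest cluster number scanned (>= 1).
#' @param k Optional fixed cluster number, bypassing the saturation scan.
#' @param seed Seed (clustering itself is deterministic; recorded for
#'   provenance).
#' @param saturation_tol Relative-decrease tolerance (default 0.01).
#' @param metric `"pearson"` (default) or `"spearman"` correlation.
#' @param features Feature genes (default from `x`).
#' @param pseudocount Log-transform pseudocount.
#' @return Object of class `cluster_model`: labels, medoids, k, the distance
#'   matrix, the dispersion path, outlier flags (all FALSE until
#'   [detect_outliers()]), and parameters.
#' @export
cluster_cells <- function(x, k_max = 10, k = NULL, seed = 1,
                          saturation_tol = 0.01, metric = "pearson",
                          features = NULL, pseudocount = 0.1) {
  if (k_max < 1) stop_config("k_max must be >= 1")
  d <- correlation_distance(x, features = features, pseudocount = pseudocount,
                            method = metric)
  n <- nrow(d)
  cells <- rownames(d)
  k_max <- min(max(k_max, k %||% 1L), n)

  partition_at <- function(kk) {
    if (kk == 1) return(setNames(rep(1L, n), cells))
    fit <- withr::with_seed(seed, cluster::pam(stats::as.dist(d), kk,
                                               do.swap = TRUE))
    setNames(as.integer(fit$clustering), cells)
  }
  within_dispersion <- function(labels) {
    med <- compute_medoids(d, labels)
    sum(d[cbind(cells, med[as.character(labels)])])
  }

  labels_k <- lapply(seq_len(k_max), partition_at)
  w <- vapply(labels_k, within_dispersion, numeric(1))

  if (!is.null(k)) {
    k_sel <- as.integer(min(k, n))
  } else {
    dec <- -diff(w) # D(k) = W(k) - W(k+1), defined for k < k_max
    k_sel <- k_max
    for (kk in seq_along(dec)) {
      rel <- dec[kk] / max(w[kk], .Machine$double.eps)
      collapsed <- kk >= 2 && dec[kk] < 0.5 * dec[kk - 1]
      if (rel < saturation_tol || collapsed || w[kk] <= 0) {
        k_sel <- kk
        break
      }
    }
  }
  k_sel <- as.integer(k_sel)
  labels <- labels_k[[k_sel]]
  medoids <- compute_medoids(d, labels)
  structure(list(
    labels = labels,
    medoids = medoids,
    k = k_sel,
    dist = d,
    dispersion_path = tibble::tibble(k = seq_len(k_max), within = w),
    outlier = setNames(rep(FALSE, n), cells),
    params = list(k_max = k_max, seed = seed,
                  saturation_tol = saturation_tol, metric = metric,
                  pseudocount = pseudocount),
    features = features
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d cells in %d clusters (%d outliers)\n",
              length(x$labels), x$k, sum(x$outlier)))
  invisible(x)
}

#' Flag outlier cells under the negative-binomial background model
#'
#' For every cell and feature gene, computes the tail probability of the
#' observed count under NB(cluster mean, background variance): the smaller of
#' P(X <= x) and P(X >= x). A cell is an outlier iff at least
#' `min_outlier_genes` genes have tail probability below `probthr`
#' (default 1e-4). Outliers are flagged (not re-clustered) and excluded from
#' the subsequent medoid computation.
#'
#' @param model A `cluster_model`.
#' @param x The `transcript_counts` the model was fitted on.
#' @param noise A `background_model`.
#' @param probthr Outlier tail-probability threshold (default 1e-4;
#'   `probthr = 0` flags nothing).
#' @param min_outlier_genes Minimum number of outlier genes per outlier cell
#'   (default 2).
#' @return The `cluster_model` with `outlier` flags set, medoids recomputed
#'   on non-outlier members, and a per-cell `outlier_genes` count.
#' @export
detect_outliers <- function(model, x, noise, probthr = 1e-4,
                            min_outlier_genes = 2) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(noise, "background_model"))
  counts <- as_count_matrix(x)
  features <- model$features %||%
    (if (inherits(x, "transcript_counts")) x$feature_genes else rownames(counts))
  cm <- counts[features, names(model$labels), drop = FALSE]
  n_out <- setNames(integer(length(model$labels)), names(model$labels))
  for (cl in sort(unique(model$labels))) {
    members <- names(model$labels)[model$labels == cl]
    mu <- rowMeans(cm[, members, drop = FALSE])
    ok <- mu > 0
    if (!any(ok)) next
    size <- nb_size_from_model(noise, mu[ok])
    for (cell in members) {
      obs <- round(cm[ok, cell])
      p_lo <- pnbinom(obs, mu = mu[ok], size = size)
      p_hi <- 1 - pnbinom(obs - 1, mu = mu[ok], size = size)
      p <- pmin(p_lo, p_hi)
      n_out[cell] <- sum(p < probthr)
    }
  }
  model$outlier <- n_out >= min_outlier_genes
  if (probthr <= 0) model$outlier[] <- FALSE
  model$outlier_genes <- n_out
  model$medoids <- compute_medoids(model$dist, model$labels,
                                   exclude = names(model$outlier)[model$outlier])
  model
}
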