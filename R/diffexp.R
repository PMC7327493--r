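#' Exact conditional negative-binomial test for two summed counts
#'
#' Tests whether the split of a total count T = kA + kB between two groups is
#' compatible with the groups' negative-binomial distributions. With P_A and
#' P_B the NB mass functions of the group sums, the p-value is the
#' probability, conditional on the total, of any split at most as likely as
#' the observed one:
#' `p = sum over a + b = T with P_A(a) P_B(b) <= P_A(kA) P_B(kB)
#'      of P_A(a) P_B(b) / sum over a + b = T of P_A(a) P_B(b)`.
#' The test is symmetric under swapping the groups. For totals above
#' `crossover` the conditional distribution is replaced by a Laplace normal
#' approximation around its mode (documented approximation; continuous at the
#' crossover to well below typical decision thresholds).
#'
#' @param k_a,k_b Observed summed counts (non-negative; non-integers are
#'   rounded with a warning).
#' @param mu_a,mu_b NB means of the group sums.
#' @param size_a,size_b NB size parameters of the group sums (see
#'   [nb_group_params()]).
#' @param crossover Total above which the normal approximation is used.
#' @return Raw p-value in (0, 1].
#' @export
nb_exact_test <- function(k_a, k_b, mu_a, mu_b, size_a, size_b,
                          crossover = 5000) {
  if (k_a < 0 || k_b < 0) stop_data("negative counts")
  if (k_a != round(k_a) || k_b != round(k_b)) {
    warn("non-integer counts rounded for the exact test")
    k_a <- round(k_a); k_b <- round(k_b)
  }
  total <- k_a + k_b
  if (total == 0) return(1)
  if (total <= crossover) {
    a <- 0:total
    joint <- dnbinom(a, mu = mu_a, size = size_a) *
      dnbinom(total - a, mu = mu_b, size = size_b)
    denom <- sum(joint)
    if (denom == 0) return(1)
    obs <- joint[k_a + 1]
    # small relative slack guards against ties lost to roundoff
    min(1, sum(joint[joint <= obs * (1 + 1e-7)]) / denom)
  } else {
    log_joint <- function(a) {
      dnbinom(a, mu = mu_a, size = size_a, log = TRUE) +
        dnbinom(total - a, mu = mu_b, size = size_b, log = TRUE)
    }
    # the conditional log-mass is concave in a; locate its mode on a grid
    # refined around the coarse optimum
    grid <- unique(round(seq(0, total, length.out = 512)))
    a0 <- grid[which.max(log_joint(grid))]
    fine <- max(0, a0 - 256):min(total, a0 + 256)
    mode <- fine[which.max(log_joint(fine))]
    h <- max(1, round(total / 1000))
    d2 <- (log_joint(min(total, mode + h)) - 2 * log_joint(mode) +
             log_joint(max(0, mode - h))) / h^2
    sigma <- sqrt(-1 / min(d2, -1e-12))
    min(1, 2 * pnorm(-(abs(k_a - mode) - 0.5) / sigma))
  }
}

#' Negative-binomial parameters for a group sum
#'
#' The sum of n i.i.d. NB counts with per-cell mean m and background variance
#' v(m) is approximated by an NB with matched moments: mean `n * m`, variance
#' `n * v(m)`.
#'
#' @param mean_per_cell Per-cell mean expression m.
#' @param n_cells Number of cells in the group.
#' @param noise A `background_model`.
#' @return List with `mu` and `size` of the group-sum NB.
#' @export
nb_group_params <- function(mean_per_cell, n_cells, noise) {
  mu <- n_cells * mean_per_cell
  v <- n_cells * predict_background_variance(noise, mean_per_cell)
  size <- pmin(mu^2 / pmax(v - mu, mu / 1e6), 1e8)
  list(mu = mu, size = size)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Raw p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1 | is.na(p))) stop_data("p-values must be in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential expression between two cell groups (NB exact test)
#'
#' For each gene, the normalized counts are summed within each group and
#' rounded, and the split of the total is tested with [nb_exact_test()].
#' Under the null hypothesis both groups share the pooled per-cell mean, so
#' both group-sum NB distributions are parameterized at the pooled mean
#' through the background noise model (group means are reported for fold
#' changes). P-values are Benjamini-Hochberg corrected across all tested
#' genes.
#'
#' @param x `transcript_counts` (or matrix of normalized counts).
#' @param cells_a,cells_b Disjoint non-empty cell id vectors.
#' @param noise A `background_model`.
#' @param pseudocount Pseudocount for the reported log2 fold change.
#' @param crossover Passed to [nb_exact_test()].
#' @return Object of class `de_result`: a tibble with columns gene, mean_a,
#'   mean_b, log2fc (B over A), pval, padj, ordered by padj.
#' @export
diffexpnb <- function(x, cells_a, cells_b, noise, pseudocount = 0.1,
                      crossover = 5000) {
  counts <- as_count_matrix(x)
  if (length(intersect(cells_a, cells_b)) > 0) {
    stop_data("cell groups overlap")
  }
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    stop_data("both cell groups must be non-empty")
  }
  missing <- setdiff(c(cells_a, cells_b), colnames(counts))
  if (length(missing)) stop_data("unknown cells: %s", missing[1])
  ma <- rowMeans(counts[, cells_a, drop = FALSE])
  mb <- rowMeans(counts[, cells_b, drop = FALSE])
  k_a <- round(rowSums(counts[, cells_a, drop = FALSE]))
  k_b <- round(rowSums(counts[, cells_b, drop = FALSE]))
  n_a <- length(cells_a); n_b <- length(cells_b)
  m0 <- (k_a + k_b) / (n_a + n_b) # pooled per-cell mean under H0
  testable <- m0 > 0
  pval <- rep(NA_real_, nrow(counts))
  for (i in which(testable)) {
    pa <- nb_group_params(m0[i], n_a, noise)
    pb <- nb_group_params(m0[i], n_b, noise)
    pval[i] <- nb_exact_test(k_a[i], k_b[i], pa$mu, pb$mu, pa$size, pb$size,
                             crossover = crossover)
  }
  out <- tibble::tibble(
    gene = rownames(counts), mean_a = ma, mean_b = mb,
    log2fc = log2((mb + pseudocount) / (ma + pseudocount)),
    pval = pval
  )
  out <- dplyr::filter(out, !is.na(.data$pval))
  out$padj <- bh_adjust(out$pval)
  out <- dplyr::arrange(out, .data$padj, .data$pval, .data$gene)
  class(out) <- c("de_result", class(out))
  out
}
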