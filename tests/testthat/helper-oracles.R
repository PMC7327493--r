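# Shared fixtures and independent oracles used across the test files.

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# plain-loop conditional NB sum: the definitional brute force, kept free of
# the package's vectorized path
nb_exact_oracle <- function(k_a, k_b, mu_a, mu_b, size_a, size_b) {
  total <- k_a + k_b
  if (total == 0) return(1)
  p_obs <- dnbinom(k_a, mu = mu_a, size = size_a) *
    dnbinom(k_b, mu = mu_b, size = size_b)
  num <- 0
  den <- 0
  for (a in 0:total) {
    j <- dnbinom(a, mu = mu_a, size = size_a) *
      dnbinom(total - a, mu = mu_b, size = size_b)
    den <- den + j
    if (j <= p_obs * (1 + 1e-7)) num <- num + j
  }
  num / den
}

# all grid points of the k-simplex with step 1/steps, cached per k because
# the k = 5 grid is large
simplex_grid_cache <- new.env(parent = emptyenv())
simplex_grid <- function(k, steps = 100) {
  key <- paste(k, steps, sep = "_")
  if (!is.null(simplex_grid_cache[[key]])) return(simplex_grid_cache[[key]])
  if (k == 1) {
    grid <- matrix(steps, nrow = 1)
  } else {
    grid <- matrix(0:steps, ncol = 1)
    if (k > 2) {
      for (i in 2:(k - 1)) {
        used <- rowSums(grid)
        reps <- steps - used + 1
        grid <- grid[rep(seq_len(nrow(grid)), reps), , drop = FALSE]
        grid <- cbind(grid, sequence(reps) - 1)
      }
    }
    grid <- cbind(grid, steps - rowSums(grid))
  }
  grid <- grid / steps
  simplex_grid_cache[[key]] <- grid
  grid
}

# best achievable objective on the simplex grid (independent of the solver)
grid_search_objective <- function(M, x, steps = 100) {
  W <- simplex_grid(ncol(M), steps)
  D <- crossprod(M)
  d <- as.numeric(crossprod(M, x))
  obj <- rowSums((W %*% D) * W) - 2 * as.numeric(W %*% d) + sum(x^2)
  min(obj)
}

# small paired-stage dataset reused by several files (computed once)
demo_cache <- new.env(parent = emptyenv())
demo_pair <- function() {
  if (is.null(demo_cache$pair)) {
    cfg <- synth_config(n_genes = 300, n_cells_per_stage = 300,
                        n_clusters_a = 3, n_clusters_b = 3,
                        shared_clusters = list(c(1L, 1L), c(2L, 2L)),
                        n_marker_genes_per_cluster = 20,
                        marker_fold_change = 8, seed = 101)
    pair <- generate_stage_pair(cfg)
    qa <- suppressWarnings(run_qc(pair$stage_a, qc_config(mintotal = 100)))
    qb <- suppressWarnings(run_qc(pair$stage_b, qc_config(mintotal = 100)))
    demo_cache$pair <- list(cfg = cfg, pair = pair, qa = qa, qb = qb,
                            noise = fit_background_model(qa))
  }
  demo_cache$pair
}

# first simplex-grid composition helper check is cheap; used in stagemap tests
expect_simplex <- function(w, tol_sum = 1e-6, tol_neg = 1e-8) {
  expect_true(all(w >= -tol_neg))
  expect_lt(abs(sum(w) - 1), tol_sum)
}
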