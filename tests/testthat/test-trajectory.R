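# chained dataset with planted gradients, shared by the trajectory tests
traj_cache <- new.env(parent = emptyenv())
traj_fixture <- function() {
  if (is.null(traj_cache$fx)) {
    cfg <- synth_config(
      n_genes = 400, n_cells_per_stage = 450, n_clusters_a = 3,
      n_clusters_b = 3, shared_clusters = list(c(1L, 1L)),
      n_marker_genes_per_cluster = 15, marker_fold_change = 8,
      trajectory_chain = list(clusters = c(1L, 2L, 3L), n_early = 50,
                              n_late = 50, log2_amplitude = 3),
      seed = 77)
    pair <- generate_stage_pair(cfg)
    q <- suppressWarnings(run_qc(pair$stage_a, qc_config(mintotal = 100)))
    # the planted gradients make the chain a continuum, so the cluster
    # number is fixed as a user choice (chains are user-specified downstream)
    cl <- cluster_cells(q, k = 3)
    # recovered labels relabel the truth clusters; rebuild the chain
    ref_truth <- vapply(as.character(sort(unique(cl$labels))), function(s) {
      members <- names(cl$labels)[cl$labels == as.integer(s)]
      as.integer(names(which.max(table(pair$truth$labels_a[members]))))
    }, integer(1))
    chain <- as.integer(names(ref_truth)[match(1:3, ref_truth)])
    traj_cache$fx <- list(pair = pair, q = q, cl = cl, chain = chain)
  }
  traj_cache$fx
}

test_that("entropy has its closed-form values and bounds", {
  expect_equal(compute_entropy(rep(2, 64)), log(64))
  expect_identical(compute_entropy(c(0, 5, 0)), 0)
  expect_equal(compute_entropy(c(0.5, 0.5)), log(2))
  expect_error(compute_entropy(c(0, 0)), class = "stagemapr_data_error")
  expect_error(compute_entropy(c(-1, 2)), class = "stagemapr_data_error")
  set.seed(4)
  for (i in 1:20) {
    p <- rexp(50) * rbinom(50, 1, 0.7)
    if (sum(p) == 0) next
    h <- compute_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(sum(p > 0)) + 1e-12)
  }
})

test_that("lineage links recover the planted chain topology", {
  fx <- traj_fixture()
  lg <- infer_lineage_links(fx$cl, fx$q)
  e <- lg$edges
  key <- function(a, b) paste(sort(c(a, b)), collapse = "-")
  sig <- vapply(seq_len(nrow(e)), function(i) key(e$from[i], e$to[i]),
                character(1))[e$significant]
  chain <- fx$chain
  expect_true(key(chain[1], chain[2]) %in% sig)
  expect_true(key(chain[2], chain[3]) %in% sig)
  expect_false(key(chain[1], chain[3]) %in% sig)
  expect_true(all(e$score >= 0 & e$score <= 1))
  expect_true(all(e$pval > 0 & e$pval <= 1))
})

test_that("two clusters force a single significant link", {
  cfg <- synth_config(n_genes = 200, n_cells_per_stage = 100,
                      n_clusters_a = 2, n_clusters_b = 2,
                      shared_clusters = list(c(1L, 1L)),
                      n_marker_genes_per_cluster = 15,
                      marker_fold_change = 8, seed = 31)
  pair <- generate_stage_pair(cfg)
  q <- suppressWarnings(run_qc(pair$stage_a, qc_config(mintotal = 100)))
  cl <- cluster_cells(q, k = 2)
  lg <- infer_lineage_links(cl, q)
  expect_identical(nrow(lg$edges), 1L)
  expect_true(lg$edges$significant)
})

test_that("clusters below the size threshold leave the lineage graph", {
  fx <- traj_fixture()
  big <- max(table(fx$cl$labels))
  expect_error(infer_lineage_links(fx$cl, fx$q, cthr = big + 1),
               class = "stagemapr_data_error")
  lg <- infer_lineage_links(fx$cl, fx$q, cthr = 15)
  expect_identical(nrow(lg$vertices), 3L)
})

test_that("pseudotime follows the planted gradient order", {
  fx <- traj_fixture()
  genes <- c(fx$pair$truth$gradient_genes$early,
             fx$pair$truth$gradient_genes$late)
  traj <- pseudotime_order(fx$q, fx$chain, fx$cl, genes = genes)
  t_truth <- fx$pair$truth$pseudotime[traj$order$cell]
  expect_gte(cor(traj$order$rank, t_truth, method = "spearman"), 0.9)
  # smoothed late genes increase along the order, early genes decrease
  late_sm <- colMeans(traj$smoothed[fx$pair$truth$gradient_genes$late, ])
  expect_gt(cor(seq_along(late_sm), late_sm, method = "spearman"), 0.8)
})

test_that("reversing the chain reverses the order exactly", {
  fx <- traj_fixture()
  genes <- fx$pair$truth$gradient_genes$late[1:5]
  fwd <- pseudotime_order(fx$q, fx$chain, fx$cl, genes = genes)
  rev_traj <- pseudotime_order(fx$q, rev(fx$chain), fx$cl, genes = genes)
  expect_identical(fwd$order$cell, rev(rev_traj$order$cell))
})

test_that("constant genes smooth to flat profiles", {
  fx <- traj_fixture()
  x2 <- fx$q
  x2$counts <- rbind(x2$counts, flat_gene = rep(5, ncol(x2$counts)))
  traj <- pseudotime_order(x2, fx$chain, fx$cl, genes = "flat_gene")
  prof <- traj$smoothed["flat_gene", ]
  expect_lt(max(prof) - min(prof), 1e-6 * abs(mean(prof)))
  expect_error(pseudotime_order(fx$q, integer(0), fx$cl),
               class = "stagemapr_data_error")
})

test_that("z-scored profiles feed a SOM that separates the two waves", {
  fx <- traj_fixture()
  genes <- c(fx$pair$truth$gradient_genes$early,
             fx$pair$truth$gradient_genes$late)
  traj <- pseudotime_order(fx$q, fx$chain, fx$cl, genes = genes)
  som <- som_modules(traj, seed = 1)
  expect_identical(som$n_modules, 2L)
  m <- som$modules
  purity <- max(
    mean((m$gene %in% fx$pair$truth$gradient_genes$early) == (m$module == 1)),
    mean((m$gene %in% fx$pair$truth$gradient_genes$early) == (m$module == 2)))
  expect_gte(purity, 0.95)
  # z-score invariant: mean 0, sd 1 per gene over the order
  z <- t(scale(t(traj$smoothed)))
  expect_lt(max(abs(rowMeans(z))), 1e-6)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-6)
})

test_that("SOM training is seeded and merging is monotone in the threshold", {
  fx <- traj_fixture()
  genes <- c(fx$pair$truth$gradient_genes$early[1:20],
             fx$pair$truth$gradient_genes$late[1:20])
  traj <- pseudotime_order(fx$q, fx$chain, fx$cl, genes = genes)
  s1 <- som_modules(traj, seed = 42)
  s2 <- som_modules(traj, seed = 42)
  expect_identical(s1$modules, s2$modules)
  counts <- vapply(c(0.95, 0.85, 0.5, 0.0), function(th) {
    som_modules(traj, merge_cor = th, seed = 42)$n_modules
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicated genes double membership without new modules", {
  fx <- traj_fixture()
  genes <- c(fx$pair$truth$gradient_genes$early[1:15],
             fx$pair$truth$gradient_genes$late[1:15])
  traj <- pseudotime_order(fx$q, fx$chain, fx$cl, genes = genes)
  prof <- traj$smoothed
  dup <- rbind(prof, prof)
  rownames(dup) <- c(rownames(prof), paste0(rownames(prof), "_copy"))
  s1 <- som_modules(prof, seed = 3)
  s2 <- som_modules(dup, seed = 3)
  expect_identical(s2$n_modules, s1$n_modules)
  expect_identical(nrow(s2$modules), 2L * nrow(s1$modules))
  # each copy shares its original's module
  orig <- s2$modules$module[match(rownames(prof), s2$modules$gene)]
  copies <- s2$modules$module[match(paste0(rownames(prof), "_copy"),
                                    s2$modules$gene)]
  expect_identical(orig, copies)
})

test_that("a single gene forms a single module", {
  prof <- matrix(sin(seq(0, 3, length.out = 40)), nrow = 1,
                 dimnames = list("solo", sprintf("c%02d", 1:40)))
  s <- som_modules(prof)
  expect_identical(s$n_modules, 1L)
  expect_error(som_modules(matrix(1, 2, 10,
                                  dimnames = list(c("a", "b"), NULL))),
               class = "stagemapr_data_error")
})
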