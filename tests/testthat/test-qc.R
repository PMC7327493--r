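# small deterministic matrix builder with a controllable Kcnq1ot1 row
qc_matrix <- function(totals, kcnq_frac = rep(0, length(totals)),
                      n_genes = 5) {
  n <- length(totals)
  m <- matrix(0, nrow = n_genes + 1, ncol = n,
              dimnames = list(c("Kcnq1ot1", sprintf("g%d", seq_len(n_genes))),
                              sprintf("cell%02d", seq_len(n))))
  for (j in seq_len(n)) {
    m["Kcnq1ot1", j] <- totals[j] * kcnq_frac[j]
    rest <- totals[j] - m["Kcnq1ot1", j]
    m[-1, j] <- rest / n_genes
  }
  m
}

test_that("cell filter applies strict thresholds on total and Kcnq1ot1", {
  m <- qc_matrix(totals = c(2499, 2500, 2501, 5000, 5000, 5000),
                 kcnq_frac = c(0, 0, 0, 0.020, 0.021, 0.019))
  flt <- filter_cells(m, qc_config(mintotal = 2500))
  r <- flt$report
  # total 2499 removed, exactly 2500 retained (strict < mintotal)
  expect_identical(r$status[r$total == 2499], "removed")
  expect_identical(r$reason[r$total == 2499], "low_total")
  expect_identical(r$status[r$cell == "cell02"], "retained")
  # Kcnq1ot1 at exactly 2 percent retained; above removed (strict >)
  expect_identical(r$status[r$cell == "cell04"], "retained")
  expect_identical(r$status[r$cell == "cell05"], "removed")
  expect_identical(r$reason[r$cell == "cell05"], "kcnq_fraction")
  expect_identical(r$status[r$cell == "cell06"], "retained")
  expect_setequal(flt$retained, c("cell02", "cell03", "cell04", "cell06"))
})

test_that("removal reasons partition the cells with low_total precedence", {
  m <- qc_matrix(totals = c(1000, 5000, 4000), kcnq_frac = c(0.5, 0.5, 0))
  flt <- filter_cells(m, qc_config(mintotal = 2500))
  r <- flt$report
  # cell 1 fails both filters and is reported under low_total
  expect_identical(r$reason[1], "low_total")
  expect_identical(sum(r$reason == "low_total", na.rm = TRUE) +
                     sum(r$reason == "kcnq_fraction", na.rm = TRUE) +
                     length(flt$retained), ncol(m))
})

test_that("missing Kcnq1ot1 skips the fraction filter with a warning", {
  m <- qc_matrix(totals = c(5000, 5000))[-1, ]
  expect_warning(flt <- filter_cells(m, qc_config(mintotal = 2500)),
                 "Kcnq1ot1")
  expect_length(flt$retained, 2)
})

test_that("correlated-gene removal uses a strict threshold and drops anchors", {
  set.seed(1)
  n <- 40
  anchor <- rnorm(n, 10, 2)
  mk_cor <- function(target_r) {
    # construct a gene with an exact sample correlation to the anchor
    resid <- residuals(lm(rnorm(n) ~ anchor))
    a <- scale(anchor)[, 1]
    b <- resid / sqrt(sum(resid^2) / (n - 1))
    target_r * a + sqrt(1 - target_r^2) * b + 20
  }
  m <- rbind(anchor = anchor, same = anchor, hi = mk_cor(0.66),
             at = mk_cor(0.6499), lo = mk_cor(0.10), flat = rep(3, n))
  colnames(m) <- sprintf("c%02d", seq_len(n))
  feats <- remove_correlated_genes(m, "anchor", corr_threshold = 0.65)
  expect_false("anchor" %in% feats) # anchors leave the feature set
  expect_false("same" %in% feats)   # correlation 1.0
  expect_false("hi" %in% feats)     # 0.66 > 0.65
  expect_true("at" %in% feats)      # just below 0.65 is retained (strict)
  expect_true("lo" %in% feats)
  expect_true("flat" %in% feats)    # zero variance counts as correlation 0
  expect_error(remove_correlated_genes(m[, 1:2], "anchor"),
               class = "stagemapr_data_error")
})

test_that("downscaling equalizes totals and preserves proportions", {
  m <- matrix(c(100, 400, 500, 300, 900, 800), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  x <- normalize_downscale(m)
  expect_equal(unname(colSums(x$counts)), c(1000, 1000))
  expect_identical(x$reference_total, 1000)
  # proportions untouched
  expect_equal(x$counts[, "c2"] / sum(x$counts[, "c2"]), m[, "c2"] / sum(m[, "c2"]))
  # idempotent
  x2 <- normalize_downscale(x$counts)
  expect_equal(x2$counts, x$counts)
  # already-equal totals unchanged
  eq <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 3,
               dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  expect_equal(normalize_downscale(eq)$counts, eq)
  expect_error(normalize_downscale(cbind(m, c0 = c(0, 0, 0))),
               class = "stagemapr_data_error")
})

test_that("feature selection excludes patterns, fgenes, anchors and spike-ins", {
  set.seed(2)
  genes <- c("Sox13", "Rorc", "Rps19", "Rpl5", "Gm44044", "Malat1",
             "Kcnq1ot1", "ERCC-0001", "Pcna")
  m <- matrix(rpois(length(genes) * 20, 50), nrow = length(genes),
              dimnames = list(genes, sprintf("c%02d", 1:20)))
  x <- normalize_downscale(m)
  feats <- select_features(x, qc_config(mintotal = 10))
  expect_true(all(c("Sox13", "Rorc") %in% feats))
  expect_false("Rps19" %in% feats)    # ribosomal pattern
  expect_false("Rpl5" %in% feats)
  expect_false("Gm44044" %in% feats)  # predicted-gene pattern
  expect_false("Malat1" %in% feats)   # fgenes
  expect_false("Kcnq1ot1" %in% feats) # anchor
  expect_false("Pcna" %in% feats)     # cgenes anchor
  expect_false("ERCC-0001" %in% feats)
})

test_that("the QC cascade is order-independent for the cell filters", {
  p <- demo_pair()$pair
  counts <- correct_counts(p$stage_a)
  cfg <- qc_config(mintotal = 100)
  # totals and fractions are computed on pre-normalization counts, so the
  # report is a pure function of the input matrix
  r1 <- suppressWarnings(filter_cells(counts, cfg)$report)
  perm <- sample(ncol(counts))
  r2 <- suppressWarnings(filter_cells(counts[, perm], cfg)$report)
  expect_identical(dplyr::arrange(r1, cell), dplyr::arrange(r2, cell))
})

test_that("qc profiles carry the documented dataset cut-offs", {
  expect_identical(qc_profile("fetal_thymus")$mintotal, 2500)
  expect_identical(qc_profile("blood")$mintotal, 800)
  expect_identical(qc_profile("stimulated")$mintotal, 500)
  expect_identical(qc_profile("frozen_adult")$mintotal, 1000)
  expect_true("Gm44044" %in% qc_profile("adult_thymus")$cgenes)
  expect_true("H19" %in% qc_profile("fetal_thymus")$cgenes)
})
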