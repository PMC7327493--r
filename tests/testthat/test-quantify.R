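make_fastq <- function(records, path) {
  writeLines(unlist(lapply(records, function(r) {
    c(paste0("@", r$id), r$seq, "+", strrep("I", nchar(r$seq)))
  })), path)
  path
}

test_that("left-read layout is parsed into UMI and barcode", {
  dir <- withr::local_tempdir()
  left <- make_fastq(list(list(id = "r1", seq = paste0("AACGTTACGTAC",
                                                       strrep("T", 12)))),
                     file.path(dir, "l.fq"))
  right <- make_fastq(list(list(id = "r1", seq = "ACGT")),
                      file.path(dir, "r.fq"))
  loci <- tibble::tibble(locus = "gX", sequence = "GGGACGTGGG")
  out <- parse_read_pairs(left, right, "ACGTAC", make_exact_assigner(loci))
  expect_identical(out$umi, "AACGTT")
  expect_identical(out$barcode, "ACGTAC")
  expect_identical(out$locus, "gX")
  expect_identical(out$status, "ok")
})

test_that("multi-locus, off-whitelist and N-containing reads are excluded", {
  dir <- withr::local_tempdir()
  seqs <- c(paste0("AAAAAACCCCCC", strrep("T", 12)), # ok barcode
            paste0("AAAAAAGGGGGG", strrep("T", 12)), # off whitelist
            paste0("AANAAACCCCCC", strrep("T", 12))) # N in UMI
  left <- make_fastq(lapply(seq_along(seqs), function(i) {
    list(id = paste0("r", i), seq = seqs[i])
  }), file.path(dir, "l.fq"))
  right <- make_fastq(lapply(1:3, function(i) {
    list(id = paste0("r", i), seq = "ACGTACGT")
  }), file.path(dir, "r.fq"))
  loci <- tibble::tibble(locus = c("g1", "g2"),
                         sequence = c("TTACGTACGTTT", "CCACGTACGTCC"))
  out <- parse_read_pairs(left, right, "CCCCCC", make_exact_assigner(loci))
  expect_identical(out$status, c("multi", "off_whitelist", "ambiguous_base"))
  expect_identical(out$locus[1], "MULTI")
  m <- count_umis(out)
  expect_identical(sum(m$counts), 0L)
})

test_that("antisense matches are unmapped (sense direction only)", {
  dir <- withr::local_tempdir()
  left <- make_fastq(list(list(id = "r1", seq = paste0("AAAAAACCCCCC",
                                                       strrep("T", 12)))),
                     file.path(dir, "l.fq"))
  # read is the reverse complement of a locus substring, no sense match
  right <- make_fastq(list(list(id = "r1", seq = "TTTTGCAT")),
                      file.path(dir, "r.fq"))
  loci <- tibble::tibble(locus = "g1", sequence = "GGATGCAAAAGG")
  out <- parse_read_pairs(left, right, "CCCCCC", make_exact_assigner(loci))
  expect_identical(out$status, "unmapped")
})

test_that("malformed FASTQ fails hard with the record index", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(parse_read_pairs(path, path, "CCCCCC", identity),
               "record 2", class = "stagemapr_data_error")
  writeLines(c("@r1", "ACGT", "oops", "IIII"), path)
  expect_error(parse_read_pairs(path, path, "CCCCCC", identity),
               "record 1", class = "stagemapr_data_error")
  expect_error(parse_read_pairs(path, path, character(0), identity),
               class = "stagemapr_config_error")
})

test_that("locus merging follows the strict shorter-locus overlap rule", {
  loci <- tibble::tibble(id = c("a", "b"), chrom = "1",
                         start = c(0, 20), end = c(100, 120))
  # overlap 80 = 80% of the shorter locus (100) > 75% -> merged
  m <- merge_gene_loci(loci, 0.75)
  expect_identical(nrow(m$loci), 1L)
  expect_identical(m$loci$start, 0)
  expect_identical(m$loci$end, 120)
  expect_setequal(m$id_map$new_id, "a_b")
  # overlap 50% stays below the threshold
  loci2 <- tibble::tibble(id = c("a", "b"), chrom = "1",
                          start = c(0, 50), end = c(100, 150))
  expect_identical(nrow(merge_gene_loci(loci2, 0.75)$loci), 2L)
  # identical intervals always merge
  loci3 <- tibble::tibble(id = c("a", "b"), chrom = "1",
                          start = c(0, 0), end = c(100, 100))
  expect_identical(nrow(merge_gene_loci(loci3, 0.75)$loci), 1L)
  # exact boundary: overlap exactly 75% of the shorter is NOT merged
  loci4 <- tibble::tibble(id = c("a", "b"), chrom = "1",
                          start = c(0, 25), end = c(100, 200))
  expect_identical(nrow(merge_gene_loci(loci4, 0.75)$loci), 2L)
})

test_that("locus merging is transitive and respects chromosomes", {
  loci <- tibble::tibble(id = c("a", "b", "c", "d"), chrom = c("1", "1", "1", "2"),
                         start = c(0, 10, 20, 0), end = c(100, 110, 120, 100))
  m <- merge_gene_loci(loci, 0.75)
  # a-b and b-c overlap > 75%; a-c only 80/120... transitivity pulls c in
  expect_identical(sort(m$id_map$new_id[m$id_map$old_id %in% c("a", "b", "c")]),
                   rep("a_b_c", 3))
  expect_identical(m$id_map$new_id[m$id_map$old_id == "d"], "d")
  expect_error(merge_gene_loci(dplyr::mutate(loci, start = start - 1)),
               class = "stagemapr_data_error")
  expect_error(merge_gene_loci(loci, 0), class = "stagemapr_config_error")
})

test_that("distinct UMIs are counted once per cell and gene", {
  a <- tibble::tibble(
    read_id = sprintf("r%d", 1:4),
    barcode = "AAAAAA",
    umi = c("AAAAAA", "AAAAAA", "CCCCCC", "AAAAAA"),
    locus = c("g1", "g1", "g1", "g2"),
    status = "ok"
  )
  m <- count_umis(a)
  expect_identical(m$counts["g1", "AAAAAA"], 2L)
  expect_identical(m$counts["g2", "AAAAAA"], 1L)
  # planted duplicate rows collapse to one UMI
  dup <- dplyr::bind_rows(a, a)
  expect_identical(count_umis(dup)$counts, m$counts)
  # empty input gives an all-zero matrix over the supplied universe
  empty <- count_umis(a[0, ], cells = "AAAAAA", genes = c("g1", "g2"))
  expect_true(all(empty$counts == 0))
})

test_that("aggregation across merged loci uses the id map", {
  a <- tibble::tibble(read_id = c("r1", "r2"), barcode = "AAAAAA",
                      umi = c("AAAAAA", "CCCCCC"),
                      locus = c("iso1", "iso2"), status = "ok")
  id_map <- tibble::tibble(old_id = c("iso1", "iso2"), new_id = "gene1")
  m <- count_umis(a, id_map = id_map)
  expect_identical(m$counts["gene1", "AAAAAA"], 2L)
})

test_that("binomial collision correction has the exact closed-form anchors", {
  expect_identical(umi_to_transcripts(0), 0)
  expect_identical(umi_to_transcripts(1), 1)
  # high-precision evaluation of the closed form at near-saturation
  k <- 4095; K <- 4096
  expect_equal(umi_to_transcripts(k, K), log(1 / 4096) / log(1 - 1 / 4096),
               tolerance = 1e-12)
  # k = K clamps to K - 1 instead of diverging
  expect_identical(umi_to_transcripts(4096), umi_to_transcripts(4095))
  expect_error(umi_to_transcripts(4097), class = "stagemapr_data_error")
  expect_error(umi_to_transcripts(-1), class = "stagemapr_data_error")
})

test_that("collision correction is monotone, >= k, and -> k for large K", {
  k <- 0:4095
  t <- umi_to_transcripts(k)
  expect_true(all(diff(t) > 0))
  expect_true(all(t >= k))
  expect_true(all(abs(umi_to_transcripts(0:100, K = 1e8) - 0:100) < 0.01))
})

test_that("toy FASTQ round-trips exactly through parsing and counting", {
  fq <- generate_toy_fastq(synth_config(n_genes = 15, seed = 8),
                           reads_per_cell = 50, n_cells = 5)
  out <- parse_read_pairs(fq$fastq_left, fq$fastq_right, fq$whitelist,
                          make_exact_assigner(fq$loci))
  expect_identical(out$locus, fq$truth$locus)
  expect_identical(out$status, fq$truth$status)
  m <- count_umis(out)
  truth_umis <- dplyr::count(
    dplyr::distinct(fq$truth[fq$truth$status == "ok", ],
                    barcode, locus, umi), locus, barcode)
  for (i in seq_len(nrow(truth_umis))) {
    expect_identical(m$counts[truth_umis$locus[i], truth_umis$barcode[i]],
                     truth_umis$n[i])
  }
  expect_identical(sum(m$counts), sum(truth_umis$n))
})

test_that("corrupted reads are flagged consistently with the generator", {
  fq <- generate_toy_fastq(synth_config(n_genes = 12, seed = 9),
                           reads_per_cell = 40, n_cells = 5,
                           multimap_frac = 0.1, off_whitelist_frac = 0.1)
  out <- parse_read_pairs(fq$fastq_left, fq$fastq_right, fq$whitelist,
                          make_exact_assigner(fq$loci))
  planted_off <- fq$truth$status == "off_whitelist"
  expect_true(all(out$status[planted_off] == "off_whitelist"))
  planted_multi <- fq$truth$status == "multi"
  expect_true(all(out$status[planted_multi] == "multi"))
})
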