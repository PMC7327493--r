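#' UMI count matrix container
#'
#' Raw genes x cells distinct-UMI counts plus cell metadata. With 6 nt UMIs
#' the UMI space has K = 4^6 = 4096 states, so no entry can exceed 4096.
#'
#' @param counts Non-negative integer matrix (genes x cells) with dimnames.
#' @param meta Optional tibble of cell metadata (must contain a `cell`
#'   column matching `colnames(counts)`).
#' @param umi_space UMI space size K (default 4096 for 6 nt UMIs).
#' @return An object of class `umi_counts`.
#' @export
umi_counts <- function(counts, meta = NULL, umi_space = 4096L) {
  assert_count_matrix(counts, "counts")
  if (any(counts > umi_space)) {
    stop_data("UMI counts exceed the UMI space size K = %d", umi_space)
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(cell = colnames(counts))
  }
  structure(list(counts = counts, meta = tibble::as_tibble(meta),
                 umi_space = as.integer(umi_space),
                 spikein = grepl("^ERCC-", rownames(counts))),
            class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf("<umi_counts> %d genes x %d cells (K = %d, %d spike-ins)\n",
              nrow(x$counts), ncol(x$counts), x$umi_space, sum(x$spikein)))
  invisible(x)
}

read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) %% 4 != 0) {
    stop_data("malformed FASTQ '%s': truncated record %d", path,
              length(lines) %/% 4 + 1)
  }
  n <- length(lines) / 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop_data("malformed FASTQ '%s': record %d", path, bad[1])
  }
  tibble::tibble(read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
                 seq = toupper(seqs))
}

#' Exact-match locus assigner for toy reads
#'
#' Builds an assigner closure that maps a cDNA read to the locus whose
#' sense-strand sequence contains it as an exact substring. Reads matching
#' more than one locus are labelled `"MULTI"`; reads matching none (including
#' antisense-only matches — assignment is in sense direction only) are
#' `"UNMAPPED"`.
#'
#' @param loci Tibble with columns `locus` and `sequence` (sense strand).
#' @return A function mapping a character vector of read sequences to locus
#'   ids / `"MULTI"` / `"UNMAPPED"`.
#' @export
make_exact_assigner <- function(loci) {
  loci <- tibble::as_tibble(loci)
  force(loci)
  function(read_seqs) {
    vapply(read_seqs, function(s) {
      hits <- which(vapply(loci$sequence, function(ref) {
        grepl(s, ref, fixed = TRUE)
      }, logical(1)))
      if (length(hits) == 0) "UNMAPPED"
      else if (length(hits) > 1) "MULTI"
      else loci$locus[hits]
    }, character(1), USE.NAMES = FALSE)
  }
}

#' Parse CEL-Seq2-layout paired reads into per-read assignments
#'
#' The left read carries the barcode information: the first six bases are the
#' unique molecular identifier (UMI), the next six the cell barcode, and the
#' remainder a polyT stretch. The right read is assigned to a gene locus by
#' `locus_assigner`. Reads with off-whitelist barcodes, ambiguous bases (N)
#' in UMI/barcode, missing polyT, multi-locus matches or no match are flagged
#' and excluded from counting; the per-reason tally is attached as the
#' `"qc"` attribute.
#'
#' @param fastq_left,fastq_right Paths to the paired FASTQ files.
#' @param barcode_whitelist Non-empty character vector of 6 nt cell barcodes.
#' @param locus_assigner Function mapping right-read sequences to locus ids,
#'   `"MULTI"` or `"UNMAPPED"` (see [make_exact_assigner()]), or `NULL` if an
#'   external assignment table is supplied downstream.
#' @return Tibble with columns read_id, barcode, umi, locus, status
#'   (`"ok"` or an exclusion reason).
#' @export
parse_read_pairs <- function(fastq_left, fastq_right, barcode_whitelist,
                             locus_assigner) {
  if (length(barcode_whitelist) == 0) stop_config("empty barcode whitelist")
  left <- read_fastq(fastq_left)
  right <- read_fastq(fastq_right)
  if (nrow(left) != nrow(right)) {
    stop_data("read pair files differ in record count (%d vs %d)",
              nrow(left), nrow(right))
  }
  if (any(nchar(left$seq) < 13)) {
    stop_data("malformed FASTQ '%s': record %d shorter than UMI+barcode+polyT",
              fastq_left, which(nchar(left$seq) < 13)[1])
  }
  umi <- substr(left$seq, 1, 6)
  barcode <- substr(left$seq, 7, 12)
  tail_ok <- startsWith(substr(left$seq, 13, nchar(left$seq)), "T")

  status <- rep("ok", nrow(left))
  status[!tail_ok] <- "no_polyt"
  has_n <- grepl("[^ACGT]", umi) | grepl("[^ACGT]", barcode)
  status[status == "ok" & has_n] <- "ambiguous_base"
  status[status == "ok" & !barcode %in% barcode_whitelist] <- "off_whitelist"

  locus <- rep(NA_character_, nrow(left))
  live <- status == "ok"
  if (any(live)) {
    assigned <- locus_assigner(right$seq[live])
    locus[live] <- assigned
    status[live][assigned == "MULTI"] <- "multi"
    status[live][assigned == "UNMAPPED"] <- "unmapped"
  }
  locus[status != "ok"] <- ifelse(status[status != "ok"] %in%
                                    c("multi", "unmapped"),
                                  locus[status != "ok"], NA_character_)
  out <- tibble::tibble(read_id = left$read_id, barcode = barcode,
                        umi = umi, locus = locus, status = status)
  attr(out, "qc") <- dplyr::count(out, .data$status, name = "reads")
  out
}

#' Merge overlapping gene loci into gene groups
#'
#' Two loci on the same chromosome merge when their overlap length strictly
#' exceeds `overlap_fraction` of the shorter locus; merging is closed
#' transitively (union-find), and a merged group's interval is the union of
#' its members. Coordinates are 0-based half-open.
#'
#' @param loci Tibble with columns `id`, `chrom`, `start`, `end` (and
#'   optionally `strand`).
#' @param overlap_fraction Fraction of the shorter locus that must be
#'   exceeded, in `(0, 1]`; default 0.75.
#' @return List with `loci` (merged tibble) and `id_map` (tibble old id ->
#'   merged id).
#' @export
merge_gene_loci <- function(loci, overlap_fraction = 0.75) {
  loci <- tibble::as_tibble(loci)
  if (overlap_fraction <= 0 || overlap_fraction > 1) {
    stop_config("overlap_fraction must be in (0, 1]")
  }
  if (any(loci$start < 0)) stop_data("negative locus coordinates")
  if (any(loci$start >= loci$end)) stop_data("locus with start >= end")
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, n)) {
      if (loci$chrom[i] != loci$chrom[j]) next
      ov <- min(loci$end[i], loci$end[j]) - max(loci$start[i], loci$start[j])
      shorter <- min(loci$end[i] - loci$start[i], loci$end[j] - loci$start[j])
      if (ov > overlap_fraction * shorter) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  merged <- purrr::map_dfr(groups, function(idx) {
    ids <- sort(loci$id[idx])
    strand <- if ("strand" %in% names(loci)) {
      s <- unique(loci$strand[idx])
      if (length(s) == 1) s else "*"
    } else "*"
    tibble::tibble(id = paste(ids, collapse = "_"),
                   chrom = loci$chrom[idx[1]],
                   start = min(loci$start[idx]),
                   end = max(loci$end[idx]),
                   strand = strand,
                   n_members = length(idx))
  })
  id_map <- purrr::map_dfr(seq_along(groups), function(g) {
    tibble::tibble(old_id = loci$id[groups[[g]]], new_id = merged$id[g])
  })
  list(loci = dplyr::arrange(merged, .data$chrom, .data$start),
       id_map = id_map)
}

#' Count distinct UMIs per gene and cell
#'
#' For each cell barcode the number of UMIs per transcript is counted and
#' aggregated across all transcripts derived from the same (merged) gene
#' locus: entry (g, c) is the number of distinct UMIs observed for that pair.
#' ERCC spike-in loci are counted but tagged separately in the result.
#'
#' @param assignments Read-assignment tibble from [parse_read_pairs()] or an
#'   external table with columns barcode, umi, locus (and optionally status).
#' @param id_map Optional old -> merged locus id map from [merge_gene_loci()].
#' @param cells Optional cell barcode universe fixing the column set.
#' @param genes Optional gene universe fixing the row set.
#' @return A [umi_counts()] object.
#' @export
count_umis <- function(assignments, id_map = NULL, cells = NULL, genes = NULL) {
  a <- tibble::as_tibble(assignments)
  if ("status" %in% names(a)) a <- dplyr::filter(a, .data$status == "ok")
  a <- dplyr::filter(a, !is.na(.data$locus),
                     !.data$locus %in% c("MULTI", "UNMAPPED"))
  if (!is.null(id_map)) {
    a$locus <- id_map$new_id[match(a$locus, id_map$old_id)]
  }
  a <- dplyr::distinct(a, .data$barcode, .data$locus, .data$umi)
  genes <- genes %||% sort(unique(a$locus))
  cells <- cells %||% sort(unique(a$barcode))
  counts <- matrix(0L, nrow = length(genes), ncol = length(cells),
                   dimnames = list(genes, cells))
  if (nrow(a)) {
    tab <- dplyr::count(a, .data$locus, .data$barcode)
    counts[cbind(match(tab$locus, genes), match(tab$barcode, cells))] <-
      tab$n
  }
  umi_counts(counts)
}

#' Convert observed UMI counts into transcript counts
#'
#' With K possible UMI sequences, two molecules can draw the same UMI, so the
#' number of distinct observed UMIs k underestimates the number of molecules.
#' Based on binomial occupancy statistics of a K-state UMI space, the
#' collision-corrected transcript count is
#' `t = log(1 - k/K) / log(1 - 1/K)`, with k clamped to K - 1 to avoid the
#' k = K singularity. t is non-decreasing in k, satisfies t(0) = 0 and
#' t(1) = 1 exactly, and tends to k as K grows.
#'
#' @param k Observed distinct-UMI counts (vector or matrix), `0 <= k <= K`.
#' @param K UMI space size (4096 for 6 nt UMIs).
#' @return Corrected transcript counts, same shape as `k`.
#' @export
umi_to_transcripts <- function(k, K = 4096) {
  if (any(k < 0)) stop_data("negative UMI count")
  if (any(k > K)) stop_data("UMI count exceeds UMI space size K = %s", K)
  kp <- pmin(k, K - 1)
  t <- log1p(-kp / K) / log1p(-1 / K)
  if (is.matrix(k)) dimnames(t) <- dimnames(k)
  t
}

#' Collision-correct a UMI count matrix
#'
#' @param x A [umi_counts()] object.
#' @return Genes x cells matrix of corrected transcript counts.
#' @export
correct_counts <- function(x) {
  stopifnot(inherits(x, "umi_counts"))
  umi_to_transcripts(x$counts, K = x$umi_space)
}
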