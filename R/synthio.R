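#' Configuration for the paired-stage synthetic data generator
#'
#' Defines the statistical structure of a two-stage single-cell experiment:
#' negative-binomial counts, discrete clusters with marker genes, a subset of
#' clusters shared between the stages (up to a single multiplicative stage
#' effect), optional pseudo-temporal expression gradients along a cluster
#' chain, and an optional planted sparse regulator-to-target network.
#'
#' Counts for gene g in a cell of cluster c are drawn as
#' NB(mu = m_gc, size = `nb_dispersion`), i.e. variance m + m^2/size. Shared
#' clusters use identical mean vectors in both stages, with all stage-B genes
#' multiplied by `stage_effect`, so the cross-stage correspondence remains
#' recoverable by medoid projection.
#'
#' @param n_genes Number of genes.
#' @param n_cells_per_stage Cells per stage, split evenly across clusters.
#' @param n_clusters_a,n_clusters_b Number of clusters in stage A / stage B.
#' @param shared_clusters List of two-element integer vectors `c(a, b)` pairing
#'   an A-cluster with the B-cluster that shares its mean vector.
#' @param nb_dispersion NB size parameter (must be > 0); smaller values mean
#'   stronger overdispersion.
#' @param mean_log_expression_range Range (log2 scale) from which baseline
#'   per-gene mean expression is drawn uniformly.
#' @param n_marker_genes_per_cluster Genes upregulated in each cluster.
#' @param marker_fold_change Fold change of marker genes over baseline (> 1
#'   for a real marker structure; exactly 1 disables markers).
#' @param stage_effect Multiplicative scalar applied to all stage-B means.
#' @param trajectory_chain Optional list with elements `clusters` (ordered
#'   A-cluster ids), `n_early`, `n_late` (gradient gene counts) and
#'   `log2_amplitude` (gradient amplitude in log2 units). Gradient genes have
#'   log2 mean linear in the planted pseudotime: early genes decrease, late
#'   genes increase.
#' @param planted_edges Optional tibble/data frame with columns `regulator`,
#'   `target`, `coefficient`: target counts are regenerated as Poisson draws
#'   with rate `coefficient * regulator_count + 0.1`, planting a recoverable
#'   dependence.
#' @param seed Integer seed; all generation is deterministic given it.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500,
                         n_cells_per_stage = 600,
                         n_clusters_a = 3,
                         n_clusters_b = 3,
                         shared_clusters = list(c(1L, 1L), c(2L, 2L)),
                         nb_dispersion = 2,
                         mean_log_expression_range = c(1, 5),
                         n_marker_genes_per_cluster = 20,
                         marker_fold_change = 8,
                         stage_effect = 1.5,
                         trajectory_chain = NULL,
                         planted_edges = NULL,
                         seed = 1L) {
  if (n_clusters_a < 1 || n_clusters_b < 1) {
    stop_config("each stage needs at least one cluster")
  }
  if (n_genes < 1) stop_config("gene set must be non-empty")
  if (nb_dispersion <= 0) stop_config("nb_dispersion must be positive")
  if (marker_fold_change < 1) stop_config("marker_fold_change must be >= 1")
  for (pair in shared_clusters) {
    if (length(pair) != 2 || pair[1] > n_clusters_a || pair[2] > n_clusters_b ||
        any(pair < 1)) {
      stop_config("shared_clusters pairs must reference valid cluster ids")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_stage = as.integer(n_cells_per_stage),
    n_clusters_a = as.integer(n_clusters_a),
    n_clusters_b = as.integer(n_clusters_b),
    shared_clusters = shared_clusters,
    nb_dispersion = nb_dispersion,
    mean_log_expression_range = mean_log_expression_range,
    n_marker_genes_per_cluster = as.integer(n_marker_genes_per_cluster),
    marker_fold_change = marker_fold_change,
    stage_effect = stage_effect,
    trajectory_chain = trajectory_chain,
    planted_edges = planted_edges,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a paired-stage synthetic dataset with ground truth
#'
#' Draws two stage-labelled UMI count matrices plus the full ground truth
#' needed to score every downstream stage: per-cell cluster labels, the
#' planted A/B cluster correspondence, per-cluster marker (and hence
#' differential) gene sets, planted pseudotime on the trajectory chain, and
#' the planted regulator-to-target edge list.
#'
#' @param config A [synth_config()].
#' @return A list with elements `stage_a`, `stage_b` (each of class
#'   `umi_counts`: a genes x cells count matrix plus cell metadata tibble)
#'   and `truth` (a `synth_truth` list).
#' @export
generate_stage_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_stage_pair_impl(config))
}

generate_stage_pair_impl <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  lo <- config$mean_log_expression_range
  base_mu <- 2^runif(config$n_genes, lo[1], lo[2])
  names(base_mu) <- genes

  # assign disjoint marker gene blocks: A clusters first, then B-only clusters
  shared_b <- vapply(config$shared_clusters, `[`, integer(1), 2)
  own_b <- setdiff(seq_len(config$n_clusters_b), shared_b)
  n_marker_blocks <- config$n_clusters_a + length(own_b)
  n_mark <- config$n_marker_genes_per_cluster
  if (n_marker_blocks * n_mark > config$n_genes) {
    stop_config("not enough genes for the requested marker structure")
  }
  marker_pool <- matrix(genes[seq_len(n_marker_blocks * n_mark)],
                        nrow = n_mark, ncol = n_marker_blocks)
  markers_a <- lapply(seq_len(config$n_clusters_a),
                      function(i) marker_pool[, i])
  names(markers_a) <- as.character(seq_len(config$n_clusters_a))

  mu_a <- sapply(seq_len(config$n_clusters_a), function(cl) {
    m <- base_mu
    if (config$marker_fold_change > 1) {
      m[markers_a[[cl]]] <- m[markers_a[[cl]]] * config$marker_fold_change
    }
    m
  })
  colnames(mu_a) <- as.character(seq_len(config$n_clusters_a))

  # B clusters: shared ones copy A means; own ones get their own marker block
  markers_b <- vector("list", config$n_clusters_b)
  names(markers_b) <- as.character(seq_len(config$n_clusters_b))
  mu_b <- matrix(rep(base_mu, config$n_clusters_b), ncol = config$n_clusters_b,
                 dimnames = list(genes, as.character(seq_len(config$n_clusters_b))))
  for (pair in config$shared_clusters) {
    mu_b[, pair[2]] <- mu_a[, pair[1]]
    markers_b[[pair[2]]] <- markers_a[[pair[1]]]
  }
  for (i in seq_along(own_b)) {
    block <- marker_pool[, config$n_clusters_a + i]
    if (config$marker_fold_change > 1) {
      mu_b[block, own_b[i]] <- mu_b[block, own_b[i]] * config$marker_fold_change
    }
    markers_b[[own_b[i]]] <- block
  }
  mu_b <- mu_b * config$stage_effect

  labels_a <- rep(seq_len(config$n_clusters_a),
                  length.out = config$n_cells_per_stage)
  labels_a <- sort(labels_a)
  labels_b <- sort(rep(seq_len(config$n_clusters_b),
                       length.out = config$n_cells_per_stage))

  # planted pseudotime: cluster at chain position i spans [(i-1)/L, i/L]
  chain <- config$trajectory_chain
  pseudotime_a <- rep(NA_real_, length(labels_a))
  gradient <- list(early = character(0), late = character(0))
  if (!is.null(chain)) {
    L <- length(chain$clusters)
    pos <- match(labels_a, chain$clusters)
    on_chain <- !is.na(pos)
    pseudotime_a[on_chain] <- (pos[on_chain] - 1 + runif(sum(on_chain))) / L
    used <- unlist(markers_a)
    free <- setdiff(genes, used)
    need <- chain$n_early + chain$n_late
    if (length(free) < need) stop_config("not enough free genes for gradients")
    gradient$early <- free[seq_len(chain$n_early)]
    gradient$late <- free[chain$n_early + seq_len(chain$n_late)]
  }

  draw_stage <- function(mu, labels, prefix, pseudotime = NULL) {
    n_cells <- length(labels)
    counts <- matrix(0L, nrow = config$n_genes, ncol = n_cells,
                     dimnames = list(genes, sprintf("%s%04d", prefix,
                                                    seq_len(n_cells))))
    for (j in seq_len(n_cells)) {
      m <- mu[, as.character(labels[j])]
      if (!is.null(pseudotime) && !is.na(pseudotime[j])) {
        amp <- chain$log2_amplitude
        t_j <- pseudotime[j]
        m[gradient$early] <- base_mu[gradient$early] * 2^(amp * (1 - t_j))
        m[gradient$late] <- base_mu[gradient$late] * 2^(amp * t_j)
      }
      counts[, j] <- rnbinom(config$n_genes, mu = m,
                             size = config$nb_dispersion)
    }
    counts
  }

  counts_a <- draw_stage(mu_a, labels_a, "A", pseudotime_a)
  counts_b <- draw_stage(mu_b, labels_b, "B")

  # plant regulator -> target dependence by regenerating target rows
  if (!is.null(config$planted_edges)) {
    pe <- tibble::as_tibble(config$planted_edges)
    for (i in seq_len(nrow(pe))) {
      reg <- pe$regulator[i]; tgt <- pe$target[i]
      counts_a[tgt, ] <- rpois(ncol(counts_a),
                               pe$coefficient[i] * counts_a[reg, ] + 0.1)
      counts_b[tgt, ] <- rpois(ncol(counts_b),
                               pe$coefficient[i] * counts_b[reg, ] + 0.1)
    }
  }

  names(pseudotime_a) <- colnames(counts_a)
  truth <- structure(list(
    labels_a = setNames(labels_a, colnames(counts_a)),
    labels_b = setNames(labels_b, colnames(counts_b)),
    correspondence = tibble::tibble(
      cluster_a = vapply(config$shared_clusters, `[`, integer(1), 1),
      cluster_b = vapply(config$shared_clusters, `[`, integer(1), 2)
    ),
    markers_a = markers_a,
    markers_b = markers_b,
    pseudotime = pseudotime_a,
    gradient_genes = gradient,
    planted_edges = if (is.null(config$planted_edges)) {
      tibble::tibble(regulator = character(0), target = character(0),
                     coefficient = numeric(0))
    } else {
      tibble::as_tibble(config$planted_edges)
    },
    cluster_means_a = mu_a,
    cluster_means_b = mu_b
  ), class = "synth_truth")

  list(
    stage_a = umi_counts(counts_a, meta = tibble::tibble(
      cell = colnames(counts_a), stage = "A",
      cluster_truth = labels_a)),
    stage_b = umi_counts(counts_b, meta = tibble::tibble(
      cell = colnames(counts_b), stage = "B",
      cluster_truth = labels_b)),
    truth = truth
  )
}

#' Marker-based differential gene set for a cluster pair
#'
#' The planted differential genes between two clusters of the same stage are
#' the symmetric difference of their marker sets.
#'
#' @param truth A `synth_truth` object.
#' @param cluster_1,cluster_2 Cluster ids within the stage.
#' @param stage `"A"` or `"B"`.
#' @return Character vector of planted differential genes.
#' @export
planted_de_genes <- function(truth, cluster_1, cluster_2, stage = "A") {
  markers <- if (stage == "A") truth$markers_a else truth$markers_b
  m1 <- markers[[as.character(cluster_1)]] %||% character(0)
  m2 <- markers[[as.character(cluster_2)]] %||% character(0)
  sort(union(setdiff(m1, m2), setdiff(m2, m1)))
}

#' Generate toy CEL-Seq2-layout paired FASTQ reads with a truth table
#'
#' Emits paired FASTQ files in plate-format CEL-Seq2 layout: the left read is
#' a 6 bp UMI followed by a 6 bp cell barcode and a fixed 12 nt polyT tail;
#' the right read is an exact sense-strand substring of a synthetic gene-locus
#' sequence. Configurable fractions of reads are corrupted into multimappers
#' (drawn from a cassette shared by two loci) or carry off-whitelist barcodes.
#' The returned truth table fully determines the emitted FASTQ content.
#'
#' @param config A [synth_config()]; `n_genes` loci are synthesized.
#' @param reads_per_cell Reads emitted per cell (> 0).
#' @param n_cells Number of cells; capped at 96 (one plate).
#' @param multimap_frac,off_whitelist_frac Corruption fractions in `[0, 1)`.
#' @param locus_length,read_length Locus and cDNA read lengths (nt).
#' @param dir Output directory for the two FASTQ files.
#' @return List with `fastq_left`, `fastq_right` (paths), `truth` (tibble:
#'   read_id, barcode, umi, locus, status), `loci` (tibble: locus, sequence),
#'   `whitelist` (barcodes).
#' @export
generate_toy_fastq <- function(config, reads_per_cell, n_cells = 8,
                               multimap_frac = 0, off_whitelist_frac = 0,
                               locus_length = 300, read_length = 60,
                               dir = tempdir()) {
  stopifnot(inherits(config, "synth_config"))
  if (reads_per_cell <= 0) stop_config("reads_per_cell must be positive")
  if (n_cells > 96) stop_config("plate format allows at most 96 cell barcodes")
  withr::with_seed(config$seed, {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    loci_seq <- random_dna(config$n_genes, locus_length)
    # shared cassette makes reads from it ambiguous between the first two loci
    if (config$n_genes >= 2 && multimap_frac > 0) {
      cassette <- random_dna(1, read_length + 20)
      substr(loci_seq[1], 50, 50 + nchar(cassette) - 1) <- cassette
      substr(loci_seq[2], 100, 100 + nchar(cassette) - 1) <- cassette
    }
    whitelist <- character(0)
    while (length(whitelist) < n_cells) {
      whitelist <- unique(c(whitelist, random_dna(n_cells, 6)))
    }
    whitelist <- whitelist[seq_len(n_cells)]

    n_reads <- n_cells * reads_per_cell
    barcode <- rep(whitelist, each = reads_per_cell)
    umi <- random_dna(n_reads, 6)
    locus <- sample(genes, n_reads, replace = TRUE)
    status <- rep("ok", n_reads)

    n_multi <- round(multimap_frac * n_reads)
    n_off <- round(off_whitelist_frac * n_reads)
    corrupt <- sample(n_reads, n_multi + n_off)
    idx_multi <- corrupt[seq_len(n_multi)]
    idx_off <- corrupt[n_multi + seq_len(n_off)]
    status[idx_multi] <- "multi"
    status[idx_off] <- "off_whitelist"
    for (i in idx_off) {
      repeat {
        bc <- random_dna(1, 6)
        if (!bc %in% whitelist) break
      }
      barcode[i] <- bc
    }

    right <- character(n_reads)
    for (i in seq_len(n_reads)) {
      if (status[i] == "multi") {
        right[i] <- substr(loci_seq[1], 50, 50 + read_length - 1)
        locus[i] <- NA_character_
      } else {
        start <- sample(locus_length - read_length + 1, 1)
        right[i] <- substr(loci_seq[match(locus[i], genes)], start,
                           start + read_length - 1)
      }
    }
    read_id <- sprintf("read%06d", seq_len(n_reads))
    left <- paste0(umi, barcode, strrep("T", 12))

    fq <- function(ids, seqs, path) {
      qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
      path
    }
    fastq_left <- fq(read_id, left, file.path(dir, "toy_R1.fastq"))
    fastq_right <- fq(read_id, right, file.path(dir, "toy_R2.fastq"))

    list(
      fastq_left = fastq_left,
      fastq_right = fastq_right,
      truth = tibble::tibble(read_id = read_id, barcode = barcode,
                             umi = umi, locus = locus, status = status),
      loci = tibble::tibble(locus = genes, sequence = loci_seq),
      whitelist = whitelist
    )
  })
}
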