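#' Quality-control configuration
#'
#' Parameters of the cell/gene filter cascade applied to corrected transcript
#' counts before clustering and mapping:
#'
#' * cells with a pre-filter total transcript count below `mintotal` are
#'   discarded (strict: a cell at exactly `mintotal` is retained);
#' * cells in which the low-quality marker `kcnq_gene` (Kcnq1ot1) makes up
#'   more than `kcnq_fraction` of the total are discarded (strict);
#' * genes correlating with `kcnq_gene` (Pearson r > `kcnq_corr`) are removed
#'   from the feature set, as are the anchors themselves;
#' * `fgenes` are excluded from the feature set outright; each gene in
#'   `cgenes` and everything correlating with it above `kcnq_corr` is removed
#'   from the feature set (cell-cycle / batch variability removal) while
#'   remaining in the matrix for reporting;
#' * genes matching `exclude_patterns` (ribosomal subunits, Gm-prefixed
#'   predicted genes) and ERCC spike-ins never enter the feature set.
#'
#' @param mintotal Minimum total transcripts per retained cell (> 0).
#' @param kcnq_fraction Maximum tolerated Kcnq1ot1 fraction (default 0.02).
#' @param kcnq_corr Correlation threshold for anchor-correlated gene removal
#'   (default 0.65, strict).
#' @param kcnq_gene Low-quality marker gene id.
#' @param fgenes Genes excluded from the feature set outright.
#' @param cgenes Anchor genes whose correlates are removed from features.
#' @param exclude_patterns Regular expressions for excluded gene ids.
#' @param pseudocount Pseudocount added before log transforms downstream.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(mintotal = 2500,
                      kcnq_fraction = 0.02,
                      kcnq_corr = 0.65,
                      kcnq_gene = "Kcnq1ot1",
                      fgenes = c("Malat1", "Xist"),
                      cgenes = c("Pcna", "Mki67", "Mir703", "Ptma", "Actb",
                                 "Hsp90aa1", "Hsp90ab1", "Ppia"),
                      exclude_patterns = c("^Rp[sl]", "^Gm\\d+"),
                      pseudocount = 0.1) {
  if (mintotal <= 0) stop_config("mintotal must be positive")
  if (kcnq_fraction <= 0 || kcnq_fraction >= 1) {
    stop_config("kcnq_fraction must be in (0, 1)")
  }
  if (kcnq_corr <= 0 || kcnq_corr >= 1) {
    stop_config("kcnq_corr must be in (0, 1)")
  }
  structure(list(mintotal = mintotal, kcnq_fraction = kcnq_fraction,
                 kcnq_corr = kcnq_corr, kcnq_gene = kcnq_gene,
                 fgenes = fgenes, cgenes = cgenes,
                 exclude_patterns = exclude_patterns,
                 pseudocount = pseudocount),
            class = "qc_config")
}

#' Per-dataset QC default profiles
#'
#' Named [qc_config()] presets with the total-transcript cut-offs used for
#' the different dataset types: thymus datasets at 2500 (variants at 1500 and
#' 1000 for combined fresh/frozen analyses), circulating blood cells at 800,
#' and stimulated or combined blood/lymph-node datasets at 500.
#'
#' @param name One of `"fetal_thymus"`, `"adult_thymus"`, `"blood"`,
#'   `"stimulated"`, `"lymph_combined"`, `"frozen_fetal"`, `"frozen_adult"`.
#' @param ... Overrides forwarded to [qc_config()].
#' @return A `qc_config`.
#' @export
qc_profile <- function(name = c("fetal_thymus", "adult_thymus", "blood",
                                "stimulated", "lymph_combined",
                                "frozen_fetal", "frozen_adult"), ...) {
  name <- match.arg(name)
  mintotal <- c(fetal_thymus = 2500, adult_thymus = 2500, blood = 800,
                stimulated = 500, lymph_combined = 500,
                frozen_fetal = 1500, frozen_adult = 1000)[[name]]
  adult_cgenes <- c("Pcna", "Mki67", "Mir703", "Gm44044", "Gm22757", "Gm4775",
                    "Gm17541", "Gm8225", "Gm8730", "Ptma", "Actb",
                    "Hsp90aa1", "Hsp90ab1", "Ppia")
  fetal_cgenes <- c("Malat1", "Xist", "Pcna", "Mki67", "Mir703", "Ptma",
                    "Actb", "Hsp90aa1", "Hsp90ab1", "Ppia", "H19")
  defaults <- list(mintotal = mintotal)
  if (name == "fetal_thymus") defaults$cgenes <- fetal_cgenes
  if (name == "adult_thymus") defaults$cgenes <- adult_cgenes
  args <- utils::modifyList(defaults, list(...))
  do.call(qc_config, args)
}

#' Filter cells on total transcripts and Kcnq1ot1 fraction
#'
#' A cell is removed iff its pre-filter total corrected transcript count is
#' below `mintotal` (strict) or its Kcnq1ot1 fraction exceeds
#' `kcnq_fraction` (strict). When a cell fails both, it is reported under
#' `low_total` (deterministic precedence). Both quantities are computed on
#' pre-normalization corrected counts.
#'
#' @param counts Corrected genes x cells matrix (or `umi_counts`, corrected
#'   internally).
#' @param config A [qc_config()].
#' @return List with `retained` (cell ids) and `report` (tibble: cell, total,
#'   kcnq_fraction, status, reason).
#' @export
filter_cells <- function(counts, config = qc_config()) {
  if (inherits(counts, "umi_counts")) counts <- correct_counts(counts)
  assert_count_matrix(counts)
  totals <- colSums(counts)
  if (config$kcnq_gene %in% rownames(counts)) {
    kcnq <- counts[config$kcnq_gene, ] / totals
    kcnq[totals == 0] <- 0
  } else {
    warn(sprintf("gene '%s' absent; fraction filter skipped",
                 config$kcnq_gene))
    kcnq <- rep(0, ncol(counts))
  }
  low_total <- totals < config$mintotal
  high_kcnq <- kcnq > config$kcnq_fraction
  reason <- dplyr::case_when(low_total ~ "low_total",
                             high_kcnq ~ "kcnq_fraction",
                             TRUE ~ NA_character_)
  report <- tibble::tibble(
    cell = colnames(counts), total = unname(totals),
    kcnq_fraction = unname(kcnq),
    status = ifelse(is.na(reason), "retained", "removed"),
    reason = reason
  )
  list(retained = report$cell[report$status == "retained"], report = report)
}

#' Remove genes correlated with anchor genes from a feature set
#'
#' A gene leaves the feature set iff its Pearson correlation with any anchor
#' gene across the retained cells strictly exceeds `corr_threshold`; the
#' anchors themselves are removed as well. Zero-variance genes have their
#' correlation treated as 0.
#'
#' @param counts Genes x cells matrix over retained cells.
#' @param anchor_genes Anchor gene ids (absent anchors are ignored).
#' @param corr_threshold Strict Pearson threshold (default 0.65).
#' @param features Candidate feature genes (default all rows).
#' @return Reduced feature gene character vector.
#' @export
remove_correlated_genes <- function(counts, anchor_genes,
                                    corr_threshold = 0.65,
                                    features = rownames(counts)) {
  counts <- as_count_matrix(counts)
  if (ncol(counts) < 3) stop_data("need at least 3 retained cells")
  anchors <- intersect(anchor_genes, rownames(counts))
  features <- setdiff(features, anchor_genes)
  if (length(anchors) == 0) return(features)
  suppressWarnings(
    cc <- cor(t(counts[features, , drop = FALSE]),
              t(counts[anchors, , drop = FALSE]))
  )
  cc[is.na(cc)] <- 0 # zero-variance genes
  drop <- rownames(cc)[apply(cc, 1, max) > corr_threshold]
  setdiff(features, drop)
}

#' Normalize a filtered count matrix by downscaling
#'
#' Every retained cell is rescaled to a common reference total — by default
#' the minimum retained cell total — so that all normalized cell totals are
#' equal and within-cell gene proportions are untouched. The operation is
#' idempotent.
#'
#' @param counts Corrected genes x cells matrix of retained cells.
#' @param reference `"min"` (default) or `"median"` retained total.
#' @param feature_genes Initial feature gene set (default all genes).
#' @param pseudocount Pseudocount recorded for downstream log transforms.
#' @return A `transcript_counts` object: normalized counts, pre-filter
#'   totals, reference total, feature genes.
#' @export
normalize_downscale <- function(counts, reference = c("min", "median"),
                                feature_genes = rownames(counts),
                                pseudocount = 0.1) {
  counts <- as_count_matrix(counts)
  reference <- match.arg(reference)
  totals <- colSums(counts)
  if (any(totals == 0)) stop_data("zero-total cell cannot be normalized")
  ref <- if (reference == "min") min(totals) else median(totals)
  norm <- sweep(counts, 2, ref / totals, `*`)
  structure(list(counts = norm, totals = totals, reference_total = ref,
                 feature_genes = feature_genes, pseudocount = pseudocount),
            class = "transcript_counts")
}

#' @export
print.transcript_counts <- function(x, ...) {
  cat(sprintf(
    "<transcript_counts> %d genes x %d cells, reference total %.1f, %d feature genes\n",
    nrow(x$counts), ncol(x$counts), x$reference_total,
    length(x$feature_genes)))
  invisible(x)
}

#' Select the feature gene set used for distances and mapping
#'
#' Starting from all genes, removes: genes matching the exclusion patterns
#' (ribosomal subunit genes, Gm-prefixed predicted genes), the `fgenes`
#' list, the Kcnq1ot1 anchor and its correlates, every `cgenes` anchor and
#' its correlates (Pearson r > `kcnq_corr`), and ERCC spike-ins.
#'
#' @param x A `transcript_counts` object.
#' @param config A [qc_config()].
#' @return Character vector of feature genes (hard error when empty).
#' @export
select_features <- function(x, config = qc_config()) {
  stopifnot(inherits(x, "transcript_counts"))
  genes <- rownames(x$counts)
  feats <- genes[!grepl("^ERCC-", genes)]
  for (pat in config$exclude_patterns) {
    feats <- feats[!grepl(pat, feats)]
  }
  feats <- setdiff(feats, config$fgenes)
  anchors <- intersect(c(config$kcnq_gene, config$cgenes), genes)
  if (length(anchors)) {
    feats <- remove_correlated_genes(x$counts, anchors,
                                     corr_threshold = config$kcnq_corr,
                                     features = feats)
  }
  if (length(feats) == 0) stop_data("feature gene set is empty after QC")
  feats
}

#' Run the full QC cascade
#'
#' [filter_cells()], then [normalize_downscale()], then [select_features()];
#' the QC report is attached to the result.
#'
#' @param counts Corrected matrix or `umi_counts`.
#' @param config A [qc_config()].
#' @param reference Downscaling reference, see [normalize_downscale()].
#' @return A `transcript_counts` with `feature_genes` set and a `qc_report`
#'   element.
#' @export
run_qc <- function(counts, config = qc_config(), reference = "min") {
  if (inherits(counts, "umi_counts")) counts <- correct_counts(counts)
  flt <- filter_cells(counts, config)
  if (length(flt$retained) == 0) stop_data("no cells pass the QC filters")
  x <- normalize_downscale(counts[, flt$retained, drop = FALSE],
                           reference = reference,
                           pseudocount = config$pseudocount)
  x$feature_genes <- select_features(x, config)
  x$qc_report <- flt$report
  x
}
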