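#' @importFrom rlang abort warn %||% .data
#' @importFrom stats cor var median rnbinom rpois runif rnorm pnbinom dnbinom
#'   pbinom pnorm p.adjust loess predict lm coef setNames
#' @importFrom utils head
NULL

# condition helpers: config errors and data errors are distinct classes so
# callers (and the pipeline driver) can map them to exit semantics
stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "stagemapr_config_error")
}

stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "stagemapr_data_error")
}

assert_count_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_data("`%s` must be a numeric genes x cells matrix", arg)
  }
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x)))) {
    stop_data("`%s` must have gene rownames and cell colnames", arg)
  }
  if (any(x < 0)) stop_data("`%s` contains negative counts", arg)
  invisible(x)
}

# accept either a bare matrix or one of the package's container objects
as_count_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "umi_counts") || inherits(x, "transcript_counts")) {
    return(x$counts)
  }
  stop_data("expected a matrix, umi_counts or transcript_counts object")
}

# log-transform used throughout for distances/profiles; pseudocount 0.1 is the
# package default for downscaled count data
log_profile <- function(counts, pseudocount = 0.1) {
  log2(counts + pseudocount)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

reverse_complement <- function(seqs) {
  vapply(seqs, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

pkg_version <- function() {
  as.character(utils::packageVersion("stagemapr"))
}
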