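#' Pipeline configuration
#'
#' Bundles the per-stage configurations, stage toggles and the global seed of
#' an end-to-end run on a synthetic (or externally supplied) paired-stage
#' dataset.
#'
#' @param out_dir Output directory for the TSV exports and the manifest.
#' @param seed Global seed; recorded in every output header.
#' @param synth [synth_config()] for the simulate stage (its own seed is
#'   overridden by the global seed).
#' @param qc [qc_config()] applied to both stages.
#' @param grn [grn_config()] for network inference on stage A.
#' @param chain Optional cluster chain (stage-A cluster ids) for the
#'   trajectory stage; default the truth chain when the generator planted
#'   one.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "qc", "cluster", "diffexp", "map", "trajectory", "grn")`.
#' @param input_a,input_b Optional paths to TSV count matrices used instead
#'   of the simulate stage.
#' @param k_max Cluster-number scan bound.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("stagemapr_run_"),
                            seed = 1L,
                            synth = synth_config(),
                            qc = qc_config(mintotal = 500),
                            grn = grn_config(n_trees = 100, top_edges = 100),
                            chain = NULL,
                            stages = c("simulate", "qc", "cluster", "diffexp",
                                       "map", "trajectory", "grn"),
                            input_a = NULL, input_b = NULL,
                            k_max = 8) {
  allowed <- c("simulate", "qc", "cluster", "diffexp", "map", "trajectory",
               "grn")
  if (!all(stages %in% allowed)) {
    stop_config("unknown stage: %s", setdiff(stages, allowed)[1])
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 qc = qc, grn = grn, chain = chain, stages = stages,
                 input_a = input_a, input_b = input_b, k_max = k_max),
            class = "pipeline_config")
}

# every exported TSV carries version, seed and a parameter hash in a header
# comment so runs can be matched to their configuration
write_tsv_stamped <- function(x, path, seed, param_hash) {
  header <- sprintf("# stagemapr %s seed=%d params=%s",
                    pkg_version(), seed, param_hash)
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the pipeline end to end
#'
#' Executes the toggled stages in order — simulate, qc, cluster, diffexp,
#' map (stage B onto stage A medoids), trajectory, grn — writing one TSV per
#' result and returning a manifest of files, parameters and seeds. A rerun
#' with the same configuration reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_manifest`: `files` tibble (stage, path,
#'   md5), `seed`, `param_hash`, `version`, plus the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # the output directory does not influence the results, so it stays out of
  # the parameter hash (reruns into different directories stay comparable)
  param_hash <- rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
  seed <- config$seed
  files <- list()
  results <- list()
  emit <- function(stage, name, x) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_tsv_stamped(x, path, seed, param_hash)
    files[[length(files) + 1]] <<- tibble::tibble(
      stage = stage, path = path, md5 = unname(tools::md5sum(path)))
  }

  if ("simulate" %in% config$stages) {
    sc <- config$synth
    sc$seed <- seed
    sim <- generate_stage_pair(sc)
    counts_a <- sim$stage_a$counts
    counts_b <- sim$stage_b$counts
    results$truth <- sim$truth
  } else {
    for (path in c(config$input_a, config$input_b)) {
      if (!file.exists(path)) stop_config("input path does not exist: %s", path)
    }
    read_counts <- function(path) {
      d <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
      m <- as.matrix(d[, -1])
      rownames(m) <- d[[1]]
      m
    }
    counts_a <- read_counts(config$input_a)
    counts_b <- read_counts(config$input_b)
  }

  if ("qc" %in% config$stages) {
    qc_a <- run_qc(counts_a, config$qc)
    qc_b <- run_qc(counts_b, config$qc)
    results$qc_a <- qc_a
    results$qc_b <- qc_b
    emit("qc", "qc_report_a", qc_a$qc_report)
    emit("qc", "qc_report_b", qc_b$qc_report)
  } else {
    return(finish_manifest(files, results, config, param_hash))
  }

  noise_a <- fit_background_model(qc_a)
  noise_b <- fit_background_model(qc_b)
  results$noise_a <- noise_a

  if ("cluster" %in% config$stages) {
    cl_a <- cluster_cells(qc_a, k_max = config$k_max, seed = seed)
    cl_b <- cluster_cells(qc_b, k_max = config$k_max, seed = seed)
    cl_a <- detect_outliers(cl_a, qc_a, noise_a)
    cl_b <- detect_outliers(cl_b, qc_b, noise_b)
    results$cluster_a <- cl_a
    results$cluster_b <- cl_b
    emit("cluster", "clusters_a", tidy(cl_a))
    emit("cluster", "clusters_b", tidy(cl_b))
  }

  if ("diffexp" %in% config$stages && !is.null(results$cluster_a) &&
      results$cluster_a$k >= 2) {
    labs <- results$cluster_a$labels
    de <- diffexpnb(qc_a, names(labs)[labs == 1], names(labs)[labs == 2],
                    noise_a)
    results$de <- de
    emit("diffexp", "de_cluster1_vs_2", tibble::as_tibble(de))
  }

  if ("map" %in% config$stages && !is.null(results$cluster_a)) {
    sm <- map_dataset(qc_b, qc_a, results$cluster_a)
    results$map <- sm
    emit("map", "mapping_weights", tidy(sm))
  }

  if ("trajectory" %in% config$stages && !is.null(results$cluster_a)) {
    chain <- config$chain
    if (is.null(chain) && results$cluster_a$k >= 2) {
      chain <- seq_len(min(3, results$cluster_a$k))
    }
    if (!is.null(chain)) {
      traj <- pseudotime_order(qc_a, chain, results$cluster_a)
      som <- som_modules(traj, seed = seed)
      results$trajectory <- traj
      results$som <- som
      emit("trajectory", "pseudotime", tidy(traj))
      emit("trajectory", "som_modules", tidy(som))
      links <- tryCatch(
        infer_lineage_links(results$cluster_a, qc_a,
                            cthr = min(15, floor(length(results$cluster_a$labels) /
                                                   (2 * results$cluster_a$k)))),
        stagemapr_data_error = function(e) NULL)
      if (!is.null(links)) {
        results$lineage <- links
        emit("trajectory", "lineage_links", tidy(links))
      }
    }
  }

  if ("grn" %in% config$stages) {
    grn_genes <- filter_grn_genes(qc_a, config$grn$min_transcripts,
                                  config$grn$min_cells)
    gc <- config$grn
    gc$seed <- seed
    grn <- infer_grn(qc_a, gc, genes = grn_genes)
    results$grn <- grn
    results$grn_modules <- extract_modules(grn, qc_a)
    emit("grn", "grn_edges", tidy(grn))
    emit("grn", "grn_modules", tidy(results$grn_modules))
  }

  finish_manifest(files, results, config, param_hash)
}

finish_manifest <- function(files, results, config, param_hash) {
  structure(list(
    files = if (length(files)) dplyr::bind_rows(files) else
      tibble::tibble(stage = character(0), path = character(0),
                     md5 = character(0)),
    seed = config$seed,
    param_hash = param_hash,
    version = pkg_version(),
    results = results
  ), class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> stagemapr %s, seed %d, %d output files\n",
              x$version, x$seed, nrow(x$files)))
  invisible(x)
}
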