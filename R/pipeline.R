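#' Configure the meta-program analysis
#'
#' Collects every tunable parameter of the discovery pipeline. Defaults
#' follow the conventions of cohort meta-program analyses of tumor
#' organoids: rank-15 NMF per sample, top-50 gene programs, Pearson
#' correlation of per-cell enrichment scores, Ward clustering of the
#' `1 - r` distance cut at height 1.3, and 50-gene consensus sets.
#'
#' @param k NMF rank per sample (default 15).
#' @param n_top Program size: top genes kept per factor (default 50).
#' @param cut_height Dendrogram cut height on the `1 - r` scale
#'   (default 1.3).
#' @param linkage Agglomeration method (default "average").
#' @param n_consensus Consensus gene-set size per MP (default 50).
#' @param min_programs Minimum member programs per MP (default 3).
#' @param min_samples Minimum distinct samples per MP (default 2).
#' @param min_coherence Minimum mean pairwise within-cluster score
#'   correlation for a cluster to qualify as an MP (default 0.5).
#' @param min_support Minimum consensus support for a cluster to qualify
#'   as an MP (default 0.5); see [build_metaprograms()].
#' @param min_cells Gene-detection filter threshold (default 3).
#' @param n_bins,n_ctrl Module-scoring bins and controls per gene
#'   (defaults 24 and 100).
#' @param nmf_seed Base NMF seed; sample `i` uses `nmf_seed + i`
#'   (default 42).
#' @param score_seed Module-scoring control seed (default 7).
#' @param max_iter,tol NMF stopping rule (defaults 500 and 1e-4).
#' @param restarts Seeded NMF restarts, best-of (default 1).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(k = 15, n_top = 50, cut_height = 1.3,
                            linkage = "ward.D2", n_consensus = 50,
                            min_programs = 3, min_samples = 2,
                            min_coherence = 0.5, min_support = 0.5,
                            min_cells = 3, n_bins = 24, n_ctrl = 100,
                            nmf_seed = 42L, score_seed = 7L,
                            max_iter = 500L, tol = 1e-4, restarts = 1L) {
  cfg <- list(k = k, n_top = n_top, cut_height = cut_height,
              linkage = linkage, n_consensus = n_consensus,
              min_programs = min_programs, min_samples = min_samples,
              min_coherence = min_coherence, min_support = min_support,
              min_cells = min_cells, n_bins = n_bins, n_ctrl = n_ctrl,
              nmf_seed = as.integer(nmf_seed),
              score_seed = as.integer(score_seed),
              max_iter = as.integer(max_iter), tol = tol,
              restarts = as.integer(restarts))
  if (!is_count(cfg$k) || cfg$k < 1) stop_config("`k` must be a positive integer")
  if (cfg$cut_height <= 0) stop_config("`cut_height` must be > 0")
  if (!is_count(cfg$n_consensus) || cfg$n_consensus < 1) {
    stop_config("`n_consensus` must be >= 1")
  }
  structure(cfg, class = "analysis_config")
}

#' Run the meta-program discovery pipeline on in-memory samples
#'
#' Executes the full analysis for a cohort already loaded in memory:
#' per-sample gene filtering, log1p CP10K normalization and NMF; program
#' extraction; pooled per-cell program scoring; program correlation;
#' dendrogram-cut clustering; consensus meta-program construction; and
#' per-cell MP assignment. This is the computational core behind
#' [run_pipeline()].
#'
#' @param samples Named list of [count_matrix()] objects.
#' @param config An [analysis_config()].
#' @return An `mp_result` list with elements `fits`, `programs`, `scores`,
#'   `correlation`, `partition`, `metaprograms`, `assignments` (NULL when
#'   no MP passed the filters), `composition`, and `config`.
#' @export
run_cohort <- function(samples, config = analysis_config()) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (!inherits(config, "analysis_config")) config <- do.call(analysis_config, config)

  norms <- vector("list", length(samples))
  fits <- vector("list", length(samples))
  names(norms) <- names(fits) <- names(samples)
  programs <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    cm <- samples[[i]]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("stage '%s' failed for sample %s: %s",
                      what, cm$sample_id, conditionMessage(e)),
              class = "metaprogramr_stage_error", parent = e)
      })
    }
    filtered <- stage("filter_genes", filter_genes(cm, config$min_cells))
    nm <- stage("normalize", normalize_cp10k(filtered))
    fit <- stage("nmf", nmf_factorize(
      nm, k = config$k, seed = derive_seed(config$nmf_seed, i),
      max_iter = config$max_iter, tol = config$tol,
      restarts = config$restarts
    ))
    programs[[i]] <- stage("extract_programs", extract_programs(fit, config$n_top))
    norms[[i]] <- nm
    fits[[i]] <- fit
  }
  programs <- dplyr::bind_rows(programs)
  scores <- score_programs(norms, programs, n_bins = config$n_bins,
                           n_ctrl = config$n_ctrl, seed = config$score_seed)
  correlation <- program_correlation(scores)
  partition <- cluster_programs(correlation, cut_height = config$cut_height,
                                linkage = config$linkage)
  mps <- build_metaprograms(partition, programs,
                            n_consensus = config$n_consensus,
                            min_programs = config$min_programs,
                            min_samples = config$min_samples,
                            min_coherence = config$min_coherence,
                            min_support = config$min_support,
                            correlation = correlation)
  assignments <- NULL
  composition <- NULL
  if (nrow(mps$members) > 0) {
    assignments <- assign_cells(scores, mps)
    composition <- mp_composition(assignments)
  }
  structure(
    list(fits = fits, programs = programs, scores = scores,
         correlation = correlation, partition = partition,
         metaprograms = mps, assignments = assignments,
         composition = composition, config = config),
    class = "mp_result"
  )
}

#' @exportS3Method base::print
print.mp_result <- function(x, ...) {
  cat(sprintf("<mp_result> %d samples, %d programs, %d MP(s)\n",
              length(x$fits), length(unique(x$programs$program_id)),
              length(unique(x$metaprograms$consensus$mp_id))))
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Generates a synthetic cohort with [generate_cohort()] and writes one
#' 10x-style directory per sample (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`), a YAML `manifest.yaml`, and the planted ground truth as
#' `ground_truth.json`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest tibble, invisibly.
#' @export
simulate_cohort_dir <- function(config = cohort_config(), out_dir) {
  cohort <- generate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cm in cohort$samples) {
    write_count_matrix(cm, file.path(out_dir, cm$sample_id))
  }
  manifest <- tibble(
    sample_id = names(cohort$samples),
    path = names(cohort$samples),
    group = "synthetic"
  )
  write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  write_ground_truth(cohort$truth, file.path(out_dir, "ground_truth.json"))
  invisible(manifest)
}

#' Run the pipeline from a manifest and write all artifacts
#'
#' Reads every sample named in the manifest, runs [run_cohort()], and
#' writes the stage artifacts under `out_dir`:
#' per-sample NMF factors (`nmf/<sample>_W.csv`, `nmf/<sample>_H.csv`) with
#' a JSON provenance block, per-sample program GMT files
#' (`programs/<sample>.gmt`), the pooled score table (`scores.csv`), the
#' program correlation matrix in dendrogram leaf order
#' (`correlation.csv`), MP membership (`metaprograms.json`), consensus
#' gene sets (`metaprograms.gmt`), per-cell labels (`cell_labels.csv`),
#' per-sample MP composition (`composition.csv`), a run log (`run.log`)
#' and a provenance record (`provenance.json`). A stage failure aborts
#' with the failing sample and stage named and leaves a
#' `failed/MARKER.txt` note under `out_dir`.
#'
#' @param manifest Manifest tibble or path to a YAML manifest.
#' @param out_dir Output directory.
#' @param config An [analysis_config()].
#' @return The `mp_result`, invisibly.
#' @export
run_pipeline <- function(manifest, out_dir, config = analysis_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    inform(msg)
  }
  unlink(log_path)

  samples <- list()
  for (i in seq_len(nrow(manifest))) {
    cm <- read_count_matrix(manifest$path[i], sample_id = manifest$sample_id[i])
    log_line("loaded %s: %d genes x %d cells", cm$sample_id,
             nrow(cm$counts), ncol(cm$counts))
    samples[[cm$sample_id]] <- cm
  }

  res <- tryCatch(
    run_cohort(samples, config),
    error = function(e) {
      dir.create(file.path(out_dir, "failed"), showWarnings = FALSE)
      writeLines(conditionMessage(e), file.path(out_dir, "failed", "MARKER.txt"))
      abort(conditionMessage(e), class = "metaprogramr_pipeline_error", parent = e)
    }
  )
  config <- res$config

  dir.create(file.path(out_dir, "nmf"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "programs"), showWarnings = FALSE)
  for (fit in res$fits) {
    readr::write_csv(
      as_tibble(as.data.frame(fit$W), rownames = "gene_id"),
      file.path(out_dir, "nmf", paste0(fit$sample_id, "_W.csv"))
    )
    readr::write_csv(
      as_tibble(as.data.frame(fit$H), rownames = "factor"),
      file.path(out_dir, "nmf", paste0(fit$sample_id, "_H.csv"))
    )
    jsonlite::write_json(
      list(sample_id = fit$sample_id, k = fit$k, seed = fit$seed,
           tol = config$tol, n_iter = fit$n_iter, converged = fit$converged,
           final_objective = utils::tail(fit$objective_trace, 1)),
      file.path(out_dir, "nmf", paste0(fit$sample_id, "_provenance.json")),
      auto_unbox = TRUE, digits = NA
    )
    sub <- res$programs[res$programs$sample_id == fit$sample_id, ]
    programs_to_gmt(sub, file.path(out_dir, "programs", paste0(fit$sample_id, ".gmt")))
    log_line("sample %s: NMF k=%d, %d iterations, %d programs",
             fit$sample_id, fit$k, fit$n_iter, length(unique(sub$program_id)))
  }

  write_score_csv(res$scores$scores, file.path(out_dir, "scores.csv"))
  leaf <- res$partition$hclust$order
  write_score_csv(res$correlation$r[leaf, leaf],
                  file.path(out_dir, "correlation.csv"),
                  id_col = "program_id")
  log_line("correlation stage: %d programs over %d pooled cells",
           ncol(res$scores$scores), nrow(res$scores$scores))

  jsonlite::write_json(
    list(
      mps = split(res$metaprograms$members$program_id,
                  res$metaprograms$members$mp_id),
      unclustered = res$metaprograms$unclustered$program_id,
      params = res$metaprograms$params
    ),
    file.path(out_dir, "metaprograms.json"), auto_unbox = TRUE, digits = NA
  )
  if (nrow(res$metaprograms$consensus) > 0) {
    write_gene_sets(
      tibble(set = res$metaprograms$consensus$mp_id,
             description = "consensus",
             gene = res$metaprograms$consensus$gene_id),
      file.path(out_dir, "metaprograms.gmt")
    )
  } else {
    writeLines(character(0), file.path(out_dir, "metaprograms.gmt"))
  }
  if (!is.null(res$assignments)) {
    readr::write_csv(res$assignments, file.path(out_dir, "cell_labels.csv"))
    readr::write_csv(res$composition, file.path(out_dir, "composition.csv"))
  }
  log_line("metaprograms: %d MP(s), %d unclustered program(s)",
           length(unique(res$metaprograms$consensus$mp_id)),
           nrow(res$metaprograms$unclustered))

  artifacts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "provenance.json"]
  jsonlite::write_json(
    list(
      package = "metaprogramr",
      version = as.character(utils::packageVersion("metaprogramr")),
      timestamp = format(Sys.time(), tz = "UTC"),
      config = unclass(config),
      digests = as.list(tools::md5sum(sort(artifacts)))
    ),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(res)
}
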