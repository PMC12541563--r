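#' Extract ranked gene programs from an NMF fit
#'
#' Turns each factor of an [nmf_factorize()] fit into a program: the
#' `n_top` genes with the largest loadings in that factor's W column, in
#' decreasing loading order. Ties are broken by lexicographic gene id so the
#' result is deterministic under equal loadings.
#'
#' @param fit An `nmf_fit`.
#' @param n_top Program size (default 50, the conventional signature
#'   length).
#' @return A tibble with one row per (program, gene): columns `program_id`
#'   (`<sample>_F<index>`), `sample_id`, `factor_index`, `rank`, `gene_id`,
#'   `loading`.
#' @export
extract_programs <- function(fit, n_top = 50) {
  stopifnot(inherits(fit, "nmf_fit"))
  if (!is_count(n_top) || n_top < 1) stop_config("`n_top` must be a positive integer")
  if (n_top > nrow(fit$W)) {
    stop_config(sprintf("`n_top` = %d exceeds the %d genes in the factorization",
                        n_top, nrow(fit$W)))
  }
  genes <- rownames(fit$W)
  purrr::map_dfr(seq_len(fit$k), function(j) {
    w <- fit$W[, j]
    ord <- order(-w, genes)[seq_len(n_top)]
    tibble(
      program_id = sprintf("%s_F%02d", fit$sample_id, j),
      sample_id = fit$sample_id,
      factor_index = j,
      rank = seq_len(n_top),
      gene_id = genes[ord],
      loading = unname(w[ord])
    )
  })
}

#' Export programs as a GMT gene-set collection
#'
#' @param programs Program tibble from [extract_programs()].
#' @param path GMT file path.
#' @return `path`, invisibly.
#' @export
programs_to_gmt <- function(programs, path) {
  gs <- tibble(
    set = programs$program_id,
    description = paste0("sample=", programs$sample_id),
    gene = programs$gene_id
  )
  write_gene_sets(gs, path)
}
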