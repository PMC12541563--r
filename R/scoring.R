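#' Per-cell gene-set enrichment score with binned control genes
#'
#' Scores every cell against a gene set as the mean normalized expression
#' of the set's member genes minus the mean over expression-matched control
#' genes, the convention popularized by single-cell module scorers. Genes
#' are ranked by mean normalized expression across cells and divided into
#' `n_bins` equal-frequency bins; for each member gene, `n_ctrl` control
#' genes are sampled without replacement from its bin (the member itself
#' excluded, capped at the bin's size). A random gene set therefore scores
#' near zero, and adding a constant to every gene of a cell leaves that
#' cell's score unchanged.
#'
#' Control sampling is seeded per member gene (`seed` plus the gene's
#' position in the matrix), so scores do not depend on the order in which
#' sets are scored, and shared members across sets reuse the same controls.
#'
#' @param x A `normalized_matrix` from [normalize_cp10k()], or a
#'   non-negative numeric matrix with gene rownames.
#' @param gene_set Character vector of member gene ids. Members absent from
#'   the matrix are dropped with a message; an entirely absent set is an
#'   error.
#' @param n_bins Number of equal-frequency expression bins (default 24).
#' @param n_ctrl Control genes sampled per member gene (default 100).
#' @param seed Integer seed for control sampling (default 7).
#' @param set_name Label used in messages (default "gene_set").
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(x, gene_set, n_bins = 24, n_ctrl = 100, seed = 7L,
                         set_name = "gene_set") {
  V <- if (inherits(x, "normalized_matrix")) x$values else as.matrix(x)
  if (!is_count(n_bins) || n_bins < 1) stop_config("`n_bins` must be >= 1")
  if (!is_count(n_ctrl) || n_ctrl < 1) stop_config("`n_ctrl` must be >= 1")
  bins <- expression_bins(V, n_bins)
  score_with_bins(V, bins, gene_set, n_ctrl, seed, set_name, quiet = FALSE)
}

# Equal-frequency (quantile) bins on mean expression across cells.
expression_bins <- function(V, n_bins) {
  means <- rowMeans(V)
  bin <- dplyr::ntile(means, min(n_bins, nrow(V)))
  list(bin = bin, members_of_bin = split(seq_len(nrow(V)), bin))
}

score_with_bins <- function(V, bins, gene_set, n_ctrl, seed, set_name,
                            quiet = TRUE) {
  idx <- match(gene_set, rownames(V))
  missing <- is.na(idx)
  if (all(missing)) {
    abort(sprintf("gene set '%s' has no gene present in the matrix", set_name),
          class = "metaprogramr_scoring_error")
  }
  if (any(missing) && !quiet) {
    inform(sprintf("gene set '%s': dropping %d of %d genes absent from the matrix",
                   set_name, sum(missing), length(idx)))
  }
  idx <- idx[!missing]
  ctrl <- integer(0)
  for (g in idx) {
    pool <- setdiff(bins$members_of_bin[[bins$bin[g]]], g)
    if (!length(pool)) next
    m <- min(n_ctrl, length(pool))
    picked <- with_seed(derive_seed(seed, g), {
      pool[sample.int(length(pool), m)]
    })
    ctrl <- c(ctrl, picked)
  }
  member_mean <- colMeans(V[idx, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) colMeans(V[ctrl, , drop = FALSE]) else 0
  member_mean - ctrl_mean
}

#' Score all programs on all pooled cells of a cohort
#'
#' Computes the binned-control enrichment score of every program on every
#' cell of every sample, pooling cells across samples with identifiers
#' prefixed by sample id (`<sample>_<cell>`). Each sample is scored against
#' its own expression-bin structure, and a program from one sample is scored
#' on another sample's cells through the genes the two universes share
#' (missing genes are dropped; the effective set sizes are summarized in a
#' message).
#'
#' @param norms Named list of `normalized_matrix` objects, one per sample.
#' @param programs Program tibble from [extract_programs()] (rows from all
#'   samples bound together).
#' @param n_bins,n_ctrl,seed Scoring parameters, see [module_score()].
#' @return A `score_matrix`: list with `scores` (pooled cells x programs
#'   numeric matrix), `cell_info` tibble (`cell`, `sample_id`, `cell_id`)
#'   and `params`.
#' @export
score_programs <- function(norms, programs, n_bins = 24, n_ctrl = 100,
                           seed = 7L) {
  stopifnot(is.list(norms), length(norms) >= 1)
  program_ids <- unique(programs$program_id)
  sets <- split(programs$gene_id, factor(programs$program_id, levels = program_ids))
  n_dropped <- 0L
  blocks <- vector("list", length(norms))
  cell_info <- vector("list", length(norms))
  for (i in seq_along(norms)) {
    nm <- norms[[i]]
    V <- nm$values
    bins <- expression_bins(V, n_bins)
    block <- matrix(NA_real_, nrow = ncol(V), ncol = length(program_ids),
                    dimnames = list(NULL, program_ids))
    for (p in program_ids) {
      gs <- sets[[p]]
      n_dropped <- n_dropped + sum(!(gs %in% rownames(V)))
      block[, p] <- score_with_bins(V, bins, gs, n_ctrl, seed, p, quiet = TRUE)
    }
    blocks[[i]] <- block
    cell_info[[i]] <- tibble(
      cell = paste(nm$sample_id, colnames(V), sep = "_"),
      sample_id = nm$sample_id, cell_id = colnames(V)
    )
  }
  info <- dplyr::bind_rows(cell_info)
  scores <- do.call(rbind, blocks)
  rownames(scores) <- info$cell
  if (n_dropped > 0) {
    inform(sprintf(
      "cross-sample scoring dropped %d (program, sample)-level gene entries absent from target universes",
      n_dropped))
  }
  structure(
    list(scores = scores, cell_info = info,
         params = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)),
    class = "score_matrix"
  )
}

#' @exportS3Method base::print
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d pooled cells x %d programs (n_bins = %d, n_ctrl = %d)\n",
              nrow(x$scores), ncol(x$scores), x$params$n_bins, x$params$n_ctrl))
  invisible(x)
}

#' Tidy a score matrix into long form
#'
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @return Tibble with `cell`, `sample_id`, `program_id`, `score`.
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble(
    cell = rep(rownames(x$scores), times = ncol(x$scores)),
    sample_id = rep(x$cell_info$sample_id, times = ncol(x$scores)),
    program_id = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores)
  )
}
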