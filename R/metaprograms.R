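#' Pearson correlation between program score columns
#'
#' Correlates every pair of program score vectors over all pooled cells.
#' Constant score columns (zero variance) cannot be correlated; they are
#' assigned correlation 0 with every other program (diagonal stays 1) and
#' reported in a message.
#'
#' @param s A `score_matrix` from [score_programs()], or a cells x programs
#'   numeric matrix.
#' @return A `program_correlation`: list with `r` (programs x programs
#'   symmetric matrix, unit diagonal) and `program_ids`.
#' @export
program_correlation <- function(s) {
  m <- if (inherits(s, "score_matrix")) s$scores else as.matrix(s)
  if (nrow(m) < 2) stop_contract("correlation needs at least 2 cells")
  sds <- apply(m, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    inform(sprintf("constant score column(s) set to zero correlation: %s",
                   paste(colnames(m)[const], collapse = ", ")))
  }
  r <- suppressWarnings(cor(m))
  r[is.na(r)] <- 0
  diag(r) <- 1
  structure(list(r = r, program_ids = colnames(m)),
            class = "program_correlation")
}

#' @exportS3Method base::print
print.program_correlation <- function(x, ...) {
  cat(sprintf("<program_correlation> %d programs, r in [%.2f, %.2f]\n",
              length(x$program_ids), min(x$r), max(x$r[upper.tri(x$r)] %||% 1)))
  invisible(x)
}

#' Cluster programs by cutting the correlation dendrogram
#'
#' Agglomerative clustering of programs on the distance `d = 1 - r`
#' (range 0 to 2) with the configured linkage; the tree is severed at
#' `cut_height`, so two programs share a cluster exactly when every merge
#' joining them happens at height <= `cut_height`. Merge heights live on
#' the linkage's own scale: `1 - r` of the joined pair for single/complete/
#' average linkage, accumulated merge cost for Ward.
#'
#' @param pc A `program_correlation`.
#' @param cut_height Dendrogram cut height (default 1.3).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default "ward.D2").
#' @return A `program_partition`: list with `partition` tibble
#'   (`program_id`, `cluster`), the `hclust` tree, `cut_height` and
#'   `linkage`.
#' @export
cluster_programs <- function(pc, cut_height = 1.3, linkage = "ward.D2") {
  stopifnot(inherits(pc, "program_correlation"))
  if (!is.numeric(cut_height) || cut_height <= 0) {
    stop_config("`cut_height` must be > 0")
  }
  d <- as.dist(1 - pc$r)
  hc <- hclust(d, method = linkage)
  cl <- cutree(hc, h = cut_height)
  structure(
    list(
      partition = tibble(program_id = pc$program_ids, cluster = unname(cl)),
      hclust = hc, cut_height = cut_height, linkage = linkage
    ),
    class = "program_partition"
  )
}

#' @exportS3Method base::print
print.program_partition <- function(x, ...) {
  cat(sprintf("<program_partition> %d programs in %d clusters (cut %.2f, %s linkage)\n",
              nrow(x$partition), length(unique(x$partition$cluster)),
              x$cut_height, x$linkage))
  invisible(x)
}

#' Build meta-programs from a program partition
#'
#' Clusters with at least `min_programs` member programs spanning at least
#' `min_samples` distinct samples become meta-programs (MPs). When a
#' `program_correlation` is supplied, a cluster must additionally be
#' coherent: the mean pairwise Pearson correlation among its member
#' programs' scores must reach `min_coherence`. This is the rule that
#' separates genuine meta-programs (blocks of mutually correlated programs)
#' from loose aggregates of residual factors that merely fall below the
#' dendrogram cut together. Each MP's consensus gene set holds the
#' `n_consensus` genes occurring most frequently across its member
#' programs' top-gene lists; ties are broken by better (lower) mean
#' within-program rank, then lexicographic gene id. Clusters failing the
#' filters are reported as unclustered programs.
#'
#' MPs are numbered MP1, MP2, ... by decreasing member count (ties by the
#' earliest member program).
#'
#' @param part A `program_partition` from [cluster_programs()].
#' @param programs Program tibble from [extract_programs()].
#' @param n_consensus Consensus gene-set size (default 50); the consensus
#'   has length `min(n_consensus, size of the member gene union)`.
#' @param min_programs Minimum member programs per MP (default 3).
#' @param min_samples Minimum distinct samples spanned (default 2).
#' @param min_coherence Minimum mean pairwise within-cluster correlation
#'   (default 0.5); only enforced when `correlation` is given.
#' @param min_support Minimum consensus support (default 0.5): the mean,
#'   over a candidate's consensus genes, of the fraction of member
#'   programs containing the gene. A consensus that summarizes an MP must
#'   actually recur across its members; loose clusters of residual factors
#'   have diverse top-gene lists and low support.
#' @param correlation Optional `program_correlation` used for the
#'   coherence filter.
#' @return A `metaprograms` object: list with `consensus` tibble (`mp_id`,
#'   `rank`, `gene_id`, `frequency`, `mean_rank`), `members` tibble
#'   (`mp_id`, `program_id`, `sample_id`), `unclustered` tibble, and the
#'   filter parameters.
#' @export
build_metaprograms <- function(part, programs, n_consensus = 50,
                               min_programs = 3, min_samples = 2,
                               min_coherence = 0.5, min_support = 0.5,
                               correlation = NULL) {
  stopifnot(inherits(part, "program_partition"))
  if (!is_count(n_consensus) || n_consensus < 1) {
    stop_config("`n_consensus` must be >= 1")
  }
  pt <- part$partition
  if (!all(pt$program_id %in% programs$program_id)) {
    stop_contract("partition contains programs missing from the program table")
  }
  prog_sample <- dplyr::distinct(programs, .data$program_id, .data$sample_id)
  pt <- dplyr::left_join(pt, prog_sample, by = "program_id")

  stats_tbl <- pt |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_programs = dplyr::n(),
      n_samples = dplyr::n_distinct(.data$sample_id),
      first_member = min(match(.data$program_id, part$partition$program_id)),
      .groups = "drop"
    )
  kept <- stats_tbl |>
    dplyr::filter(.data$n_programs >= min_programs,
                  .data$n_samples >= min_samples) |>
    dplyr::arrange(dplyr::desc(.data$n_programs), .data$first_member)
  if (!is.null(correlation) && nrow(kept) > 0) {
    stopifnot(inherits(correlation, "program_correlation"))
    coherence <- vapply(kept$cluster, function(cc) {
      ids <- pt$program_id[pt$cluster == cc]
      rr <- correlation$r[ids, ids, drop = FALSE]
      mean(rr[upper.tri(rr)])
    }, numeric(1))
    kept <- kept[coherence >= min_coherence, , drop = FALSE]
  }

  # consensus support: the consensus genes of a real MP recur across its
  # member programs, so their mean frequency approaches the member count
  cluster_consensus <- function(member_ids) {
    programs |>
      dplyr::filter(.data$program_id %in% member_ids) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(frequency = dplyr::n(),
                       mean_rank = mean(.data$rank), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$mean_rank, .data$gene_id) |>
      utils::head(n_consensus)
  }
  if (nrow(kept) > 0) {
    support <- vapply(kept$cluster, function(cc) {
      ids <- pt$program_id[pt$cluster == cc]
      mean(cluster_consensus(ids)$frequency) / length(ids)
    }, numeric(1))
    kept <- kept[support >= min_support, , drop = FALSE]
  }

  if (nrow(kept) == 0) {
    warn("no cluster passed the meta-program filters; returning an empty MP list")
  }
  mp_ids <- if (nrow(kept)) sprintf("MP%d", seq_len(nrow(kept))) else character(0)

  members <- purrr::map2_dfr(mp_ids, kept$cluster, function(mp, cl) {
    pt |>
      dplyr::filter(.data$cluster == cl) |>
      dplyr::transmute(mp_id = mp, .data$program_id, .data$sample_id)
  })
  consensus <- purrr::map_dfr(mp_ids, function(mp) {
    g <- cluster_consensus(members$program_id[members$mp_id == mp])
    tibble(mp_id = mp, rank = seq_len(nrow(g)), gene_id = g$gene_id,
           frequency = g$frequency, mean_rank = g$mean_rank)
  })
  if (nrow(consensus) == 0) {
    consensus <- tibble(mp_id = character(), rank = integer(),
                        gene_id = character(), frequency = integer(),
                        mean_rank = numeric())
    members <- tibble(mp_id = character(), program_id = character(),
                      sample_id = character())
  }
  unclustered <- pt |>
    dplyr::filter(!(.data$program_id %in% members$program_id)) |>
    dplyr::select("program_id", "cluster", "sample_id")
  structure(
    list(consensus = consensus, members = members, unclustered = unclustered,
         params = list(n_consensus = n_consensus, min_programs = min_programs,
                       min_samples = min_samples, min_support = min_support,
                       min_coherence = if (is.null(correlation)) NA_real_ else min_coherence)),
    class = "metaprograms"
  )
}

#' @exportS3Method base::print
print.metaprograms <- function(x, ...) {
  n <- length(unique(x$consensus$mp_id))
  cat(sprintf("<metaprograms> %d MP(s), %d member programs, %d unclustered\n",
              n, nrow(x$members), nrow(x$unclustered)))
  invisible(x)
}

#' Tidy meta-programs into their consensus gene table
#'
#' @param x A `metaprograms` object.
#' @param ... Unused.
#' @return The consensus tibble (`mp_id`, `rank`, `gene_id`, `frequency`,
#'   `mean_rank`).
#' @export
tidy.metaprograms <- function(x, ...) x$consensus

#' Per-MP summary of a meta-program set
#'
#' @param x A `metaprograms` object.
#' @param ... Unused.
#' @return Tibble with one row per MP: member program count, samples
#'   spanned, consensus size.
#' @export
glance.metaprograms <- function(x, ...) {
  if (nrow(x$members) == 0) {
    return(tibble(mp_id = character(), n_programs = integer(),
                  n_samples = integer(), n_consensus_genes = integer()))
  }
  x$members |>
    dplyr::group_by(.data$mp_id) |>
    dplyr::summarise(n_programs = dplyr::n(),
                     n_samples = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop") |>
    dplyr::left_join(
      x$consensus |>
        dplyr::group_by(.data$mp_id) |>
        dplyr::summarise(n_consensus_genes = dplyr::n(), .groups = "drop"),
      by = "mp_id"
    )
}

#' Assign each pooled cell to its best meta-program
#'
#' A cell's MP score is the mean of its member programs' score columns; the
#' cell is labeled with the arg-max MP, ties resolved toward the
#' lower-numbered MP.
#'
#' @param s A `score_matrix` from [score_programs()].
#' @param mps A `metaprograms` object with at least one MP.
#' @return Tibble with `cell`, `sample_id`, `cell_id`, `mp_id`, `mp_score`,
#'   plus one score column per MP.
#' @export
assign_cells <- function(s, mps) {
  stopifnot(inherits(s, "score_matrix"), inherits(mps, "metaprograms"))
  mp_ids <- unique(mps$members$mp_id)
  if (length(mp_ids) == 0) stop_contract("cannot assign cells with an empty MP list")
  mp_scores <- vapply(mp_ids, function(mp) {
    cols <- mps$members$program_id[mps$members$mp_id == mp]
    rowMeans(s$scores[, cols, drop = FALSE])
  }, numeric(nrow(s$scores)))
  best <- max.col(mp_scores, ties.method = "first")
  out <- dplyr::bind_cols(
    s$cell_info,
    tibble(mp_id = mp_ids[best],
           mp_score = mp_scores[cbind(seq_len(nrow(mp_scores)), best)]),
    as_tibble(mp_scores)
  )
  out
}

#' Per-sample meta-program composition
#'
#' @param assignments Output of [assign_cells()].
#' @return Tibble with `sample_id`, `mp_id`, `n_cells`, `fraction` (within
#'   sample).
#' @export
mp_composition <- function(assignments) {
  assignments |>
    dplyr::count(.data$sample_id, .data$mp_id, name = "n_cells") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(fraction = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup()
}
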