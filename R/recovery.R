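#' Score recovery of planted programs by discovered meta-programs
#'
#' Matches each planted shared program of a synthetic cohort to at most one
#' discovered meta-program by maximizing the total Jaccard overlap
#' (|intersection| / |union|) between planted gene sets and MP consensus
#' gene sets under an optimal one-to-one matching. When assignments are
#' supplied, also reports cell-label agreement: among cells with at least
#' one planted shared-program activity, the fraction whose assigned MP is
#' the one matched to their strongest planted program.
#'
#' @param truth A `ground_truth` object from [generate_cohort()].
#' @param mps A `metaprograms` object.
#' @param assignments Optional output of [assign_cells()].
#' @return A `recovery_report` list: `n_shared`, `n_mps`, `matches` tibble
#'   (`program_id`, `mp_id`, `jaccard`), `mean_jaccard` (over matched
#'   pairs; `NA` if none), and `label_agreement` (or `NA`).
#' @export
recovery_metrics <- function(truth, mps, assignments = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(mps, "metaprograms"))
  shared_ids <- truth$program_info$program_id[truth$program_info$kind == "shared"]
  planted <- lapply(setNames(shared_ids, shared_ids), function(p) {
    truth$program_genes$gene_id[truth$program_genes$program_id == p]
  })
  mp_ids <- unique(mps$consensus$mp_id)
  recovered <- lapply(setNames(mp_ids, mp_ids), function(m) {
    mps$consensus$gene_id[mps$consensus$mp_id == m]
  })

  if (length(planted) == 0 || length(recovered) == 0) {
    return(structure(
      list(n_shared = length(planted), n_mps = length(recovered),
           matches = tibble(program_id = character(), mp_id = character(),
                            jaccard = numeric()),
           mean_jaccard = NA_real_, label_agreement = NA_real_),
      class = "recovery_report"
    ))
  }

  J <- outer(seq_along(planted), seq_along(recovered),
             Vectorize(function(i, j) jaccard(planted[[i]], recovered[[j]])))
  dimnames(J) <- list(names(planted), names(recovered))
  match_idx <- best_matching(J)
  matches <- tibble(
    program_id = names(planted)[match_idx$rows],
    mp_id = names(recovered)[match_idx$cols],
    jaccard = J[cbind(match_idx$rows, match_idx$cols)]
  )

  label_agreement <- NA_real_
  if (!is.null(assignments) && nrow(matches) > 0) {
    act <- truth$cell_activity |>
      dplyr::filter(.data$program_id %in% shared_ids) |>
      dplyr::group_by(.data$sample_id, .data$cell_id) |>
      dplyr::slice_max(.data$activity, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::rename(true_program = "program_id")
    lookup <- setNames(matches$mp_id, matches$program_id)
    joined <- dplyr::inner_join(
      act, assignments[c("sample_id", "cell_id", "mp_id")],
      by = c("sample_id", "cell_id")
    )
    joined <- joined[joined$true_program %in% names(lookup), ]
    if (nrow(joined) > 0) {
      label_agreement <- mean(lookup[joined$true_program] == joined$mp_id)
    }
  }

  structure(
    list(n_shared = length(planted), n_mps = length(recovered),
         matches = matches,
         mean_jaccard = if (nrow(matches)) mean(matches$jaccard) else NA_real_,
         label_agreement = label_agreement),
    class = "recovery_report"
  )
}

#' @exportS3Method base::print
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d planted shared program(s), %d recovered MP(s), mean matched Jaccard %.3f\n",
              x$n_shared, x$n_mps, x$mean_jaccard))
  if (!is.na(x$label_agreement)) {
    cat(sprintf("  cell-label agreement: %.3f\n", x$label_agreement))
  }
  invisible(x)
}

#' One-row summary of a recovery report
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return One-row tibble with `n_shared`, `n_mps`, `mean_jaccard`,
#'   `label_agreement`.
#' @export
glance.recovery_report <- function(x, ...) {
  tibble(n_shared = x$n_shared, n_mps = x$n_mps,
         mean_jaccard = x$mean_jaccard, label_agreement = x$label_agreement)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Optimal one-to-one matching maximizing sum of J over injections of the
# smaller index set into the larger. Exhaustive for small problems (the
# intended use: a handful of planted programs vs a handful of MPs), greedy
# beyond that.
best_matching <- function(J) {
  n <- nrow(J); m <- ncol(J)
  transposed <- FALSE
  if (n > m) {
    J <- t(J); tmp <- n; n <- nrow(J); m <- ncol(J); transposed <- TRUE
  }
  n_inj <- prod((m - n + 1):m)
  if (n_inj <= 5e5) {
    best <- NULL; best_val <- -Inf
    rec <- function(i, used, cols, val) {
      if (i > n) {
        if (val > best_val) {
          best_val <<- val; best <<- cols
        }
        return(invisible())
      }
      for (j in seq_len(m)) {
        if (!used[j]) {
          used[j] <- TRUE
          rec(i + 1, used, c(cols, j), val + J[i, j])
          used[j] <- FALSE
        }
      }
    }
    rec(1L, logical(m), integer(0), 0)
    rows <- seq_len(n); cols <- best
  } else {
    rows <- integer(0); cols <- integer(0)
    used_r <- logical(n); used_c <- logical(m)
    for (step in seq_len(n)) {
      Jm <- J
      Jm[used_r, ] <- -Inf; Jm[, used_c] <- -Inf
      ij <- arrayInd(which.max(Jm), dim(Jm))
      rows <- c(rows, ij[1]); cols <- c(cols, ij[2])
      used_r[ij[1]] <- TRUE; used_c[ij[2]] <- TRUE
    }
    o <- order(rows); rows <- rows[o]; cols <- cols[o]
  }
  if (transposed) list(rows = cols, cols = rows) else list(rows = rows, cols = cols)
}
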