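#' Filter genes by detection frequency
#'
#' Retains genes detected (count > 0) in at least `min_cells` cells,
#' preserving gene order; cells are unchanged. Applied per sample before
#' normalization so that downstream factorization never sees all-zero rows.
#'
#' @param x A [count_matrix()].
#' @param min_cells Minimum number of cells a gene must be detected in
#'   (default 3).
#' @return A filtered [count_matrix()].
#' @export
filter_genes <- function(x, min_cells = 3) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is_count(min_cells)) stop_config("`min_cells` must be a non-negative integer")
  keep <- Matrix::rowSums(x$counts > 0) >= min_cells
  if (!any(keep)) {
    stop_contract(sprintf("no gene is detected in >= %d cells of sample %s",
                          min_cells, x$sample_id))
  }
  count_matrix(x$sample_id, x$counts[keep, , drop = FALSE])
}

#' Library-size normalize to log1p counts-per-10k
#'
#' Computes `log1p(count / libsize * 1e4)` per entry, with library sizes
#' taken within the sample. Cells with zero total count are dropped with a
#' warning. The result is non-negative and zero exactly where the count is
#' zero, satisfying the input contract of [nmf_factorize()] and of the
#' module scorer.
#'
#' @param x A [count_matrix()].
#' @return A `normalized_matrix`: list with `sample_id` and dense `values`
#'   (genes x cells, non-negative).
#' @export
normalize_cp10k <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  libsize <- Matrix::colSums(x$counts)
  drop <- libsize == 0
  counts <- x$counts
  if (any(drop)) {
    warn(sprintf("dropping %d zero-count cell(s) from sample %s",
                 sum(drop), x$sample_id))
    counts <- counts[, !drop, drop = FALSE]
    libsize <- libsize[!drop]
  }
  values <- as.matrix(counts %*% Matrix::Diagonal(x = 1e4 / libsize))
  values <- log1p(values)
  dimnames(values) <- dimnames(counts)
  structure(
    list(sample_id = x$sample_id, values = values),
    class = "normalized_matrix"
  )
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> sample %s: %d genes x %d cells (log1p CP10K)\n",
              x$sample_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}
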