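#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes one sample's non-negative normalized expression matrix
#' \eqn{X \approx W H} (genes x k and k x cells, both entrywise
#' non-negative) by minimizing the Frobenius reconstruction error
#' \eqn{\|X - WH\|_F} with Lee-Seung multiplicative updates.
#'
#' Initialization is seeded random-uniform scaled by `sqrt(mean(X) / k)`.
#' Iteration stops when the relative objective decrease over one iteration
#' falls below `tol`, or at `max_iter`. A small floor (1e-10) in every
#' denominator prevents division by zero. On return, factors are ordered by
#' decreasing `||W_j||_2 * ||H_j||_2` and each W column is normalized to
#' unit L2 norm with its scale folded into the matching H row, so "top genes
#' per factor" is well defined and comparable across runs.
#'
#' With `restarts > 1` the factorization is repeated from seeds
#' `seed, seed + 1, ...` and the run with the lowest final objective is
#' returned.
#'
#' @param x A `normalized_matrix` from [normalize_cp10k()], or any
#'   non-negative numeric matrix with dimnames.
#' @param k Number of factors (rank).
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum number of update iterations (default 500).
#' @param tol Relative objective-decrease stopping tolerance (default 1e-4).
#' @param restarts Number of seeded runs to take the best of (default 1).
#' @return An `nmf_fit` with fields `sample_id`, `k`, `W`, `H`,
#'   `objective_trace`, `seed`, `n_iter`, `converged`.
#' @export
#' @examples
#' x <- matrix(rpois(300, 4), 30, 10,
#'             dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:10)))
#' fit <- nmf_factorize(x, k = 3, seed = 1)
#' glance(fit)
nmf_factorize <- function(x, k, seed = 42L, max_iter = 500L, tol = 1e-4,
                          restarts = 1L) {
  if (inherits(x, "normalized_matrix")) {
    sample_id <- x$sample_id
    X <- x$values
  } else {
    sample_id <- attr(x, "sample_id") %||% "sample"
    X <- as.matrix(x)
  }
  if (any(X < 0)) stop_contract("NMF input must be non-negative")
  if (!is_count(k) || k < 1) stop_config("`k` must be a positive integer")
  if (k > min(dim(X))) {
    stop_config(sprintf("k = %d exceeds matrix dimensions %d x %d",
                        k, nrow(X), ncol(X)))
  }
  if (!is_count(max_iter) || max_iter < 1) stop_config("`max_iter` must be >= 1")
  if (!is.numeric(tol) || tol <= 0) stop_config("`tol` must be > 0")
  if (!is_count(restarts) || restarts < 1) stop_config("`restarts` must be >= 1")

  best <- NULL
  for (r in seq_len(restarts)) {
    s <- derive_seed(seed, r - 1L)
    fit <- nmf_run(X, k, s, max_iter, tol)
    if (is.null(best) ||
        utils::tail(fit$objective_trace, 1) < utils::tail(best$objective_trace, 1)) {
      best <- fit
    }
  }
  best$sample_id <- sample_id
  best
}

nmf_run <- function(X, k, seed, max_iter, tol) {
  eps <- 1e-10
  g <- nrow(X); n <- ncol(X)
  init_scale <- sqrt(mean(X) / k)
  WH <- with_seed(seed, list(
    W = matrix(runif(g * k), g, k) * init_scale,
    H = matrix(runif(k * n), k, n) * init_scale
  ))
  W <- WH$W; H <- WH$H
  x_ss <- sum(X^2)
  trace <- numeric(0)
  converged <- FALSE
  prev <- NA_real_
  for (it in seq_len(max_iter)) {
    # H update, then W update (one Lee-Seung iteration)
    WtX <- crossprod(W, X)
    WtW <- crossprod(W)
    H <- H * WtX / (WtW %*% H + eps)
    XHt <- tcrossprod(X, H)
    HHt <- tcrossprod(H)
    W <- W * XHt / (W %*% HHt + eps)
    # Frobenius objective via the trace identity (no full WH product):
    # ||X - WH||^2 = ||X||^2 - 2 <W, X H'> + <W'W, H H'>
    # XHt and HHt are unchanged by the W update and are reused.
    WtW <- crossprod(W)
    obj2 <- x_ss - 2 * sum(W * XHt) + sum(WtW * HHt)
    obj <- sqrt(max(obj2, 0))
    trace <- c(trace, obj)
    if (!is.na(prev)) {
      rel <- (prev - obj) / max(prev, eps)
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
    prev <- obj
  }
  # order factors by joint norm, fold W-column scale into H
  wn <- sqrt(colSums(W^2))
  hn <- sqrt(rowSums(H^2))
  ord <- order(wn * hn, decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  wn <- wn[ord]
  wn[wn == 0] <- 1
  W <- sweep(W, 2, wn, "/")
  H <- sweep(H, 1, wn, "*")
  fac_ids <- sprintf("F%02d", seq_len(k))
  dimnames(W) <- list(rownames(X), fac_ids)
  dimnames(H) <- list(fac_ids, colnames(X))
  structure(
    list(sample_id = NA_character_, k = k, W = W, H = H,
         objective_trace = trace, seed = seed, n_iter = length(trace),
         converged = converged),
    class = "nmf_fit"
  )
}

#' @exportS3Method base::print
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "<nmf_fit> sample %s: k = %d, %d genes x %d cells, %d iterations (%s), final ||X-WH||_F = %.4g\n",
    x$sample_id, x$k, nrow(x$W), ncol(x$H), x$n_iter,
    if (x$converged) "converged" else "max_iter reached",
    utils::tail(x$objective_trace, 1)
  ))
  invisible(x)
}

#' Tidy an NMF fit into a long loading table
#'
#' @param x An `nmf_fit`.
#' @param ... Unused.
#' @return Tibble with columns `factor`, `gene_id`, `loading`.
#' @export
tidy.nmf_fit <- function(x, ...) {
  tibble(
    factor = rep(colnames(x$W), each = nrow(x$W)),
    gene_id = rep(rownames(x$W), times = ncol(x$W)),
    loading = as.vector(x$W)
  )
}

#' One-row summary of an NMF fit
#'
#' @param x An `nmf_fit`.
#' @param ... Unused.
#' @return One-row tibble with `sample_id`, `k`, `n_iter`, `converged`,
#'   `final_objective`.
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(
    sample_id = x$sample_id, k = x$k, n_iter = x$n_iter,
    converged = x$converged,
    final_objective = utils::tail(x$objective_trace, 1)
  )
}

#' Plot the NMF objective trace
#'
#' @param object An `nmf_fit`.
#' @param ... Unused.
#' @return A ggplot of Frobenius error against iteration.
#' @export
autoplot.nmf_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective_trace),
               objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "Frobenius error",
                  title = sprintf("NMF objective, sample %s (k = %d)",
                                  object$sample_id, object$k)) +
    ggplot2::theme_minimal()
}
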