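# Candidate-column designs for the greedy solver.
#
# Two flavours share one interface: a dense matrix of main-effect columns,
# and a virtual design over all pairwise product columns generated block-wise,
# so the full n x k(k-1)/2 interaction matrix never has to exist in memory.
# The solver only ever asks a design for (a) per-column sums of squares,
# (b) cross-products with an n-vector, and (c) a few materialized columns.

new_design <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "eben_design")
}

#' Dense main-effect candidate design
#'
#' Wraps a samples-by-features numeric matrix as a candidate design for
#' [eben_fit()]. Columns are used exactly as provided (the solver does not
#' re-center or re-scale them).
#'
#' @param X numeric matrix, samples in rows, candidate features in columns.
#' @return An `eben_design` object.
#' @export
main_effect_design <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("design matrix contains non-finite values")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  new_design("dense",
             X = X, n = nrow(X), K = ncol(X),
             keys = colnames(X), xx = unname(colSums(X^2)))
}

#' Pairwise interaction candidate design
#'
#' A virtual design whose candidate columns are centered elementwise products
#' `X[, i] * X[, j]` over feature pairs. Columns are generated on demand in
#' blocks of `block` pairs, so scan memory stays bounded by `block * n`
#' regardless of how many pairs are enumerated. Product columns are centered
#' by their own mean (computed over the rows of `X` supplied here); the raw
#' products themselves are never re-normalized.
#'
#' @param X numeric matrix of (normalized) base features, samples in rows.
#' @param pairs integer matrix with two columns `(i, j)`, `i < j`; defaults to
#'   all `k(k-1)/2` pairs from [enumerate_interactions()].
#' @param block number of pair columns materialized at a time.
#' @return An `eben_design` object.
#' @export
interaction_design <- function(X, pairs = NULL, block = 1000L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("design matrix contains non-finite values")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(pairs)) pairs <- enumerate_interactions(ncol(X))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || any(pairs[, 1] >= pairs[, 2]) ||
      any(pairs < 1L) || any(pairs > ncol(X))) {
    stop("'pairs' must be a two-column matrix of canonical indices i < j")
  }
  storage.mode(pairs) <- "integer"
  block <- max(1L, as.integer(block))
  m <- nrow(pairs)
  means <- numeric(m)
  xx <- numeric(m)
  n <- nrow(X)
  for (start in seq(1L, m, by = block)) {
    idx <- start:min(start + block - 1L, m)
    P <- X[, pairs[idx, 1], drop = FALSE] * X[, pairs[idx, 2], drop = FALSE]
    mu <- colMeans(P)
    means[idx] <- mu
    xx[idx] <- colSums(P^2) - n * mu^2
  }
  keys <- paste(colnames(X)[pairs[, 1]], colnames(X)[pairs[, 2]], sep = ":")
  new_design("pairs",
             X = X, n = n, K = m, keys = keys,
             pairs = pairs, means = means, xx = xx, block = block)
}

design_ncand <- function(d) d$K

# Materialize candidate columns `idx` as an n x length(idx) matrix.
design_cols <- function(d, idx) {
  if (d$kind == "dense") {
    d$X[, idx, drop = FALSE]
  } else {
    P <- d$X[, d$pairs[idx, 1], drop = FALSE] * d$X[, d$pairs[idx, 2], drop = FALSE]
    sweep(P, 2L, d$means[idx], "-")
  }
}

# Cross-product of every candidate column with an n-vector v (length-K result),
# computed block-wise for pair designs.
design_cross_vec <- function(d, v) {
  if (d$kind == "dense") return(unname(drop(crossprod(d$X, v))))
  out <- numeric(d$K)
  sv <- sum(v)
  for (start in seq(1L, d$K, by = d$block)) {
    idx <- start:min(start + d$block - 1L, d$K)
    P <- d$X[, d$pairs[idx, 1], drop = FALSE] * d$X[, d$pairs[idx, 2], drop = FALSE]
    out[idx] <- drop(crossprod(P, v)) - d$means[idx] * sv
  }
  out
}

# Columns for candidates `idx` evaluated on NEW base data, using the centering
# constants learned from the design's own rows (needed for held-out prediction).
design_newdata_cols <- function(d, idx, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (length(idx) == 0L) return(matrix(0, nrow(Xnew), 0L))
  if (d$kind == "dense") {
    Xnew[, idx, drop = FALSE]
  } else {
    P <- Xnew[, d$pairs[idx, 1], drop = FALSE] * Xnew[, d$pairs[idx, 2], drop = FALSE]
    sweep(P, 2L, d$means[idx], "-")
  }
}
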