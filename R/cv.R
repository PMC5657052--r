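# Hyperparameter selection by k-fold cross-validated prediction error.

#' Balanced cross-validation folds
#'
#' Deterministic given the seed; fold sizes differ by at most one and every
#' sample lands in exactly one fold.
#'
#' @param n number of samples.
#' @param n_folds number of folds, `2 <= n_folds <= n`.
#' @param seed integer seed for the fold assignment.
#' @return Integer vector of fold labels in `1..n_folds`, length `n`.
#' @export
make_folds <- function(n, n_folds, seed = 1L) {
  n <- as.integer(n); n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("need at least 2 folds")
  if (n_folds > n) stop("more folds (", n_folds, ") than samples (", n, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

#' Cross-validation grid specification
#'
#' @param lambda1_values,lambda2_values non-negative candidate values.
#' @param n_folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return A list of class `cv_grid`.
#' @export
cv_grid <- function(lambda1_values, lambda2_values, n_folds = 5L, seed = 1L) {
  stopifnot(length(lambda1_values) >= 1L, length(lambda2_values) >= 1L,
            all(lambda1_values >= 0), all(lambda2_values >= 0),
            n_folds >= 2L)
  structure(list(lambda1_values = as.numeric(lambda1_values),
                 lambda2_values = as.numeric(lambda2_values),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cv_grid")
}

#' Data-scaled default hyperparameter ladder
#'
#' The inclusion gate compares `q^2 - s` against `lambda1 + 2*lambda2`, and at
#' the empty model with noise variance `var(y)` the gate statistics scale with
#' the sample size. The default grid is therefore a log-spaced ladder anchored
#' at `lambda_max = max_k(q_k^2 - s_k)` evaluated at that null scale -- the
#' smallest gate value that excludes every candidate -- times the given
#' ratios (the usual penalized-regression convention). The default ladder
#' spans two decades below `lambda_max` in four geometric steps; ratios much
#' below 0.01 buy little additional signal under a sparse model while letting
#' the scan admit (and pay for) very large noise models.
#'
#' @param design an `eben_design` (or a plain matrix of candidates).
#' @param y phenotype vector.
#' @param ratios multipliers applied to `lambda_max`.
#' @return Numeric ladder of candidate penalty values, largest first.
#' @export
lambda_ladder <- function(design, y, ratios = 10^seq(0, -2, length.out = 4)) {
  d <- if (inherits(design, "eben_design")) design else main_effect_design(design)
  yt <- y - mean(y)
  s0 <- sum(yt^2) / length(yt)
  if (s0 <= 0) stop("phenotype is constant")
  q2 <- design_cross_vec(d, yt)^2 / s0
  lmax <- max(q2 - d$xx)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  sort(lmax * ratios, decreasing = TRUE)
}

default_cv_grid <- function(design, y, n_folds = 5L, seed = 1L) {
  lad <- lambda_ladder(design, y)
  cv_grid(lad, lad, n_folds = n_folds, seed = seed)
}

#' Cross-validated prediction error of one hyperparameter pair
#'
#' For each fold, fits EBEN on the complement, predicts `mu + X_test beta`
#' over the selected features, and accumulates the held-out squared error. A
#' failed fold fit scores the pair as `+Inf`.
#'
#' @param X samples-by-features base matrix.
#' @param y phenotype vector.
#' @param lambda1,lambda2 hyperparameters to score.
#' @param folds fold labels from [make_folds()].
#' @param control solver settings.
#' @param design_builder function mapping a row-subset of `X` to an
#'   `eben_design`; defaults to [main_effect_design()].
#' @param max_cv_iterations iteration budget for the scoring fits. Grid
#'   points whose penalties are far too lax admit very large noise models
#'   that converge slowly; truncating them still yields the (poor) held-out
#'   error that makes cross-validation reject them, at a fraction of the
#'   cost. Final fits at the chosen pair are not affected.
#' @return List with `mse` (mean over folds of the fold MSE), `se` (its
#'   standard error across folds) and `per_fold`.
#' @export
cv_score <- function(X, y, lambda1, lambda2, folds,
                     control = eben_control(),
                     design_builder = main_effect_design,
                     max_cv_iterations = 250L) {
  X <- as.matrix(X)
  stopifnot(length(folds) == nrow(X), length(y) == nrow(X))
  control$max_iterations <- min(control$max_iterations,
                                as.integer(max_cv_iterations))
  nf <- max(folds)
  per_fold <- vapply(seq_len(nf), function(f) {
    tr <- folds != f
    tryCatch({
      dtr <- design_builder(X[tr, , drop = FALSE])
      fit <- suppressWarnings(eben_fit(dtr, y[tr], lambda1, lambda2, control))
      pred <- predict_eben(fit, dtr, X[!tr, , drop = FALSE])
      mean((y[!tr] - pred)^2)
    }, error = function(e) Inf)
  }, numeric(1))
  list(mse = mean(per_fold),
       se = sd(per_fold) / sqrt(nf),
       per_fold = per_fold)
}

#' Select hyperparameters by cross-validation
#'
#' Scores every grid point with [cv_score()] on a shared fold assignment and
#' returns the minimizer of the mean held-out squared error. Ties are broken
#' toward the sparser model, i.e. the larger effective gate `lambda1 +
#' 2*lambda2` (then larger `lambda2`, then larger `lambda1`).
#'
#' @param X samples-by-features base matrix.
#' @param y phenotype vector.
#' @param grid a [cv_grid()]; `NULL` uses the data-scaled default ladder.
#' @param control solver settings.
#' @param design_builder,max_cv_iterations as in [cv_score()].
#' @return List with `lambda1`, `lambda2`, `report` (one row per grid point:
#'   lambda1, lambda2, cv_mse, cv_se) and the fold assignment.
#' @export
select_hyperparams <- function(X, y, grid = NULL, control = eben_control(),
                               design_builder = main_effect_design,
                               max_cv_iterations = 250L) {
  X <- as.matrix(X)
  if (is.null(grid)) grid <- default_cv_grid(design_builder(X), y)
  stopifnot(inherits(grid, "cv_grid"))
  control$max_iterations <- min(control$max_iterations,
                                as.integer(max_cv_iterations))
  folds <- make_folds(nrow(X), grid$n_folds, grid$seed)
  pts <- expand.grid(lambda1 = grid$lambda1_values,
                     lambda2 = grid$lambda2_values,
                     KEEP.OUT.ATTRS = FALSE)
  nf <- grid$n_folds
  mse <- matrix(NA_real_, nrow(pts), nf)
  for (f in seq_len(nf)) {
    tr <- folds != f
    dtr <- tryCatch(design_builder(X[tr, , drop = FALSE]),
                    error = function(e) NULL)
    Xte <- X[!tr, , drop = FALSE]
    yte <- y[!tr]
    for (g in seq_len(nrow(pts))) {
      mse[g, f] <- tryCatch({
        if (is.null(dtr)) stop("design construction failed")
        fit <- suppressWarnings(
          eben_fit(dtr, y[tr], pts$lambda1[g], pts$lambda2[g], control))
        mean((yte - predict_eben(fit, dtr, Xte))^2)
      }, error = function(e) Inf)
    }
  }
  cv_mse <- rowMeans(mse)
  cv_se <- apply(mse, 1L, function(r) {
    if (all(is.finite(r))) sd(r) / sqrt(nf) else NA_real_
  })
  if (all(!is.finite(cv_mse))) stop("all grid points failed cross-validation")
  best <- min(cv_mse[is.finite(cv_mse)])
  tied <- which(is.finite(cv_mse) & cv_mse <= best + 1e-12)
  ord <- order(pts$lambda1[tied] + 2 * pts$lambda2[tied],
               pts$lambda2[tied], pts$lambda1[tied], decreasing = TRUE)
  chosen <- tied[ord[1L]]
  report <- data.frame(lambda1 = pts$lambda1, lambda2 = pts$lambda2,
                       cv_mse = cv_mse, cv_se = cv_se)
  report$chosen <- seq_len(nrow(report)) == chosen
  list(lambda1 = pts$lambda1[chosen], lambda2 = pts$lambda2[chosen],
       report = report, folds = folds)
}
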