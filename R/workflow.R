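# The four-step epistasis analysis:
#   1. main-effect scan on y,
#   2. phenotype correction y' = y - X'_m beta'_m over the significant mains,
#   3. exhaustive pairwise interaction scan on y',
#   4. unified re-estimation of the selected mains + pairs against the
#      original y, reporting only terms significant in the joint model.
# Each step runs its own hyperparameter cross-validation.

#' Enumerate canonical feature pairs
#'
#' All `k(k-1)/2` pairs `(i, j)` with `i < j`, in lexicographic order.
#'
#' @param k number of features, at least 2.
#' @return Integer matrix with columns `i`, `j`.
#' @export
enumerate_interactions <- function(k) {
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 features to form pairs")
  i <- rep.int(seq_len(k - 1L), (k - 1L):1L)
  j <- sequence((k - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Build one centered interaction column
#'
#' The elementwise product of two normalized feature columns, centered by its
#' own mean. Identical to the column the block-streamed [interaction_design()]
#' generates.
#'
#' @param X samples-by-features matrix.
#' @param i,j column indices with `i != j`.
#' @return Numeric n-vector.
#' @export
build_interaction_column <- function(X, i, j) {
  stopifnot(i >= 1, j >= 1, i <= ncol(X), j <= ncol(X), i != j)
  p <- X[, i] * X[, j]
  p - mean(p)
}

#' Step 1: scan for main effects
#'
#' Cross-validates the hyperparameters over the main-effect columns only, then
#' fits EBEN on the full data at the chosen pair. Significance is `p <
#' control$p_threshold` (0.05 by default).
#'
#' @param X normalized samples-by-features matrix.
#' @param y phenotype vector aligned with `X`.
#' @param grid optional [cv_grid()]; default is the data-scaled ladder.
#' @param control solver settings.
#' @param folds,seed fold count and seed used when `grid` is `NULL`.
#' @return An `eben_fit` with the CV report attached as `$cv`.
#' @export
scan_main_effects <- function(X, y, grid = NULL, control = eben_control(),
                              folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(grid)) {
    grid <- cv_grid(lambda_ladder(main_effect_design(X), y),
                    lambda_ladder(main_effect_design(X), y),
                    n_folds = folds, seed = seed)
  }
  sel <- select_hyperparams(X, y, grid, control, main_effect_design)
  fit <- eben_fit(main_effect_design(X), y, sel$lambda1, sel$lambda2, control)
  fit$cv <- sel
  fit
}

#' Step 2: derive the corrected phenotype
#'
#' Subtracts the fitted contributions of the significant main effects:
#' `y' = y - X'_m beta'_m`. The phenotype mean is not subtracted; the
#' interaction scan re-estimates its own mean. With no significant main
#' effects `y' = y`.
#'
#' @param y original phenotype.
#' @param X the matrix the main fit was produced on.
#' @param main_fit the Step-1 `eben_fit`.
#' @return List with `y_prime` and `removed` (feature, beta of each
#'   subtracted term).
#' @export
correct_phenotype <- function(y, X, main_fit) {
  stopifnot(inherits(main_fit, "eben_fit"))
  coef <- main_fit$coefficients
  sig <- coef[coef$significant, , drop = FALSE]
  if (!all(sig$feature %in% colnames(X))) {
    stop("main fit features not found in X: ",
         paste(setdiff(sig$feature, colnames(X)), collapse = ", "))
  }
  y_prime <- as.numeric(y)
  if (nrow(sig)) {
    y_prime <- y_prime - drop(X[, sig$feature, drop = FALSE] %*% sig$beta)
  }
  list(y_prime = stats::setNames(y_prime, rownames(X)),
       removed = data.frame(feature = sig$feature, beta = sig$beta,
                            stringsAsFactors = FALSE))
}

#' Step 3: scan for epistatic effects on the corrected phenotype
#'
#' EBEN over all pairwise centered product columns (main-effect columns are
#' not candidates at this stage), with its own hyperparameter
#' cross-validation. Pair columns are streamed in blocks, so memory stays
#' bounded by `block * n`.
#'
#' @param X normalized samples-by-features matrix.
#' @param y_prime corrected phenotype from [correct_phenotype()] (the
#'   `y_prime` vector or the list itself).
#' @param grid optional [cv_grid()].
#' @param control solver settings.
#' @param folds,seed fold count and seed used when `grid` is `NULL`.
#' @param block pair-columns block size for streaming.
#' @return An `eben_fit` over interaction keys, with `$pairs` (the selected
#'   index pairs) and the CV report attached.
#' @export
scan_epistasis <- function(X, y_prime, grid = NULL, control = eben_control(),
                           folds = 5L, seed = 1L, block = 1000L) {
  X <- as.matrix(X)
  if (is.list(y_prime)) y_prime <- y_prime$y_prime
  builder <- function(Xsub) interaction_design(Xsub, block = block)
  if (is.null(grid)) {
    lad <- lambda_ladder(builder(X), y_prime)
    grid <- cv_grid(lad, lad, n_folds = folds, seed = seed)
  }
  sel <- select_hyperparams(X, y_prime, grid, control, builder)
  d <- builder(X)
  fit <- eben_fit(d, y_prime, sel$lambda1, sel$lambda2, control)
  fit$cv <- sel
  fit$pairs <- d$pairs[fit$active, , drop = FALSE]
  fit
}

#' Step 4: unified re-estimation of selected mains and pairs
#'
#' Joint EBEN fit of the Step-1 significant main-effect columns and the
#' Step-3 significant interaction columns against the original phenotype,
#' with fresh cross-validation. Only terms significant in this joint model
#' are reported.
#'
#' @param X normalized samples-by-features matrix.
#' @param main_features character vector of selected main-effect feature
#'   names (columns of `X`).
#' @param pairs integer matrix (i, j) of selected interaction index pairs.
#' @param y original phenotype.
#' @param grid optional [cv_grid()].
#' @param control solver settings.
#' @param folds,seed fold count and seed used when `grid` is `NULL`.
#' @return An `eben_workflow` result (see [run_workflow()]).
#' @export
fit_unified_model <- function(X, main_features, pairs, y, grid = NULL,
                              control = eben_control(), folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  pairs <- if (is.null(pairs) || !length(pairs)) {
    matrix(integer(0), 0, 2)
  } else {
    matrix(as.integer(pairs), ncol = 2)
  }
  n_main <- length(main_features)
  n_pair <- nrow(pairs)
  empty <- data.frame(feature_1 = character(0), feature_2 = character(0),
                      beta = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  if (n_main + n_pair == 0L) {
    warning("no features selected in Steps 1 and 3; returning empty result")
    return(new_workflow_result(empty, empty, fit = NULL))
  }
  cols <- cbind(
    if (n_main) X[, main_features, drop = FALSE] else NULL,
    if (n_pair) vapply(seq_len(n_pair), function(r) {
      build_interaction_column(X, pairs[r, 1], pairs[r, 2])
    }, numeric(nrow(X))) else NULL
  )
  pair_keys <- if (n_pair) {
    paste(colnames(X)[pairs[, 1]], colnames(X)[pairs[, 2]], sep = ":")
  } else character(0)
  colnames(cols) <- c(main_features, pair_keys)
  if (is.null(grid)) {
    lad <- lambda_ladder(main_effect_design(cols), y)
    grid <- cv_grid(lad, lad, n_folds = min(folds, nrow(cols)), seed = seed)
  }
  sel <- select_hyperparams(cols, y, grid, control, main_effect_design)
  fit <- eben_fit(main_effect_design(cols), y, sel$lambda1, sel$lambda2, control)
  fit$cv <- sel
  coef <- fit$coefficients
  coef <- coef[coef$significant, , drop = FALSE]
  is_pair <- coef$feature %in% pair_keys
  main_rows <- data.frame(feature_1 = coef$feature[!is_pair],
                          feature_2 = rep("", sum(!is_pair)),
                          beta = coef$beta[!is_pair], se = coef$se[!is_pair],
                          t = coef$t[!is_pair], p = coef$p[!is_pair],
                          stringsAsFactors = FALSE)
  split_keys <- strsplit(coef$feature[is_pair], ":", fixed = TRUE)
  pair_rows <- data.frame(
    feature_1 = vapply(split_keys, `[`, "", 1L),
    feature_2 = vapply(split_keys, `[`, "", 2L),
    beta = coef$beta[is_pair], se = coef$se[is_pair],
    t = coef$t[is_pair], p = coef$p[is_pair],
    stringsAsFactors = FALSE)
  new_workflow_result(main_rows, pair_rows, fit = fit)
}

new_workflow_result <- function(main_rows, pair_rows, fit = NULL,
                                steps = list(), alpha_level = 0.05,
                                seed = NA_integer_) {
  rownames(main_rows) <- NULL
  rownames(pair_rows) <- NULL
  unified <- rbind(
    if (nrow(main_rows)) cbind(effect_type = "main", main_rows) else NULL,
    if (nrow(pair_rows)) cbind(effect_type = "epistatic", pair_rows) else NULL
  )
  if (is.null(unified)) {
    unified <- data.frame(effect_type = character(0), feature_1 = character(0),
                          feature_2 = character(0), beta = numeric(0),
                          se = numeric(0), t = numeric(0), p = numeric(0),
                          stringsAsFactors = FALSE)
  }
  structure(list(main = main_rows, epistasis = pair_rows, unified = unified,
                 unified_fit = fit, steps = steps,
                 alpha_level = alpha_level, seed = seed),
            class = "eben_workflow")
}

#' @export
print.eben_workflow <- function(x, ...) {
  cat("EBEN epistasis workflow result\n")
  cat(sprintf("  %d main effect(s), %d epistatic pair(s) at p < %g\n",
              nrow(x$main), nrow(x$epistasis), x$alpha_level))
  if (nrow(x$unified)) print(x$unified, digits = 4)
  invisible(x)
}

#' Run the four-step epistasis workflow
#'
#' Executes the main-effect scan, phenotype correction, pairwise epistasis
#' scan and unified re-estimation in order, each with its own cross-validated
#' hyperparameters. Deterministic given the seed.
#'
#' @param X normalized samples-by-features matrix (see
#'   [inverse_quantile_normalize()]).
#' @param y phenotype vector aligned with the rows of `X`.
#' @param alpha_level per-step significance level (0.05 by default).
#' @param folds cross-validation fold count.
#' @param seed integer seed; fold assignments for Steps 1, 3 and 4 derive
#'   from it.
#' @param block pair-columns block size for the Step-3 streaming scan.
#' @param fdr if `TRUE`, apply Benjamini-Hochberg correction to each step's
#'   p-values before thresholding (off by default; the workflow's native rule
#'   is raw p < alpha_level).
#' @return An object of class `eben_workflow`: `main` and `epistasis` tables
#'   (the Step-4-significant terms), the combined `unified` table, and
#'   per-step provenance in `steps`.
#' @export
run_workflow <- function(X, y, alpha_level = 0.05, folds = 5L, seed = 1L,
                         block = 1000L, fdr = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 10L) {
    stop("refusing to run the workflow with fewer than 10 samples")
  }
  stopifnot(length(y) == nrow(X), alpha_level > 0, alpha_level < 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  control <- eben_control(p_threshold = alpha_level)
  seed <- as.integer(seed)

  adjust <- function(fit) {
    if (fdr && nrow(fit$coefficients)) {
      fit$coefficients$significant <-
        p.adjust(fit$coefficients$p, method = "BH") < alpha_level
    }
    fit
  }

  # Step 1: main effects on y
  main_fit <- adjust(scan_main_effects(X, y, control = control,
                                       folds = folds, seed = seed))
  sig_main <- main_fit$coefficients[main_fit$coefficients$significant, ,
                                    drop = FALSE]

  # Step 2: corrected phenotype
  corr <- correct_phenotype(y, X, main_fit)

  # Step 3: epistasis on y'
  epi_fit <- adjust(scan_epistasis(X, corr$y_prime, control = control,
                                   folds = folds, seed = seed + 1L,
                                   block = block))
  sig_epi <- epi_fit$coefficients[epi_fit$coefficients$significant, ,
                                  drop = FALSE]
  sig_pairs <- epi_fit$pairs[epi_fit$coefficients$significant, , drop = FALSE]

  # Step 4: unified model against the original y
  result <- fit_unified_model(X, sig_main$feature, sig_pairs, y,
                              control = control, folds = folds,
                              seed = seed + 2L)
  if (fdr && !is.null(result$unified_fit)) {
    fit <- adjust(result$unified_fit)
    coef <- fit$coefficients
    # rebuild the result tables under the adjusted significance flags
    pair_keys <- paste(colnames(X)[sig_pairs[, 1]],
                       colnames(X)[sig_pairs[, 2]], sep = ":")
    coef <- coef[coef$significant, , drop = FALSE]
    is_pair <- coef$feature %in% pair_keys
    sk <- strsplit(coef$feature[is_pair], ":", fixed = TRUE)
    result <- new_workflow_result(
      data.frame(feature_1 = coef$feature[!is_pair],
                 feature_2 = rep("", sum(!is_pair)),
                 beta = coef$beta[!is_pair], se = coef$se[!is_pair],
                 t = coef$t[!is_pair], p = coef$p[!is_pair],
                 stringsAsFactors = FALSE),
      data.frame(feature_1 = vapply(sk, `[`, "", 1L),
                 feature_2 = vapply(sk, `[`, "", 2L),
                 beta = coef$beta[is_pair], se = coef$se[is_pair],
                 t = coef$t[is_pair], p = coef$p[is_pair],
                 stringsAsFactors = FALSE),
      fit = fit)
  }
  result$alpha_level <- alpha_level
  result$seed <- seed
  result$steps <- list(
    step1 = list(lambda1 = main_fit$lambda1, lambda2 = main_fit$lambda2,
                 n_selected = nrow(main_fit$coefficients),
                 n_significant = nrow(sig_main),
                 cv = main_fit$cv$report),
    step2 = list(removed = corr$removed),
    step3 = list(lambda1 = epi_fit$lambda1, lambda2 = epi_fit$lambda2,
                 n_selected = nrow(epi_fit$coefficients),
                 n_significant = nrow(sig_epi),
                 cv = epi_fit$cv$report),
    step4 = if (!is.null(result$unified_fit)) {
      list(lambda1 = result$unified_fit$lambda1,
           lambda2 = result$unified_fit$lambda2,
           cv = result$unified_fit$cv$report)
    } else {
      list(lambda1 = NA_real_, lambda2 = NA_real_, cv = NULL)
    },
    folds = folds, block = block, fdr = fdr
  )
  result
}
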