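# Synthetic data with planted truth, drawn from the generative model
#   y = mu + X beta_m + X_i X_j beta_e + e,   e ~ N(0, sigma^2),
# with X simulated i.i.d. standard normal and then inverse-quantile-normalized
# per column, matching the distribution of the pipeline's real inputs.

#' Specify a synthetic ground truth
#'
#' @param n,k sample and feature counts (`n >= 10`, `k >= 2`).
#' @param mains data frame with columns `feature` (index in `1..k`) and
#'   `beta`, or `NULL` for no main effects.
#' @param pairs data frame with columns `feature_i`, `feature_j`, `beta`;
#'   pairs are canonicalized to `i < j`.
#' @param noise_sd residual standard deviation sigma (> 0).
#' @param mu phenotype mean.
#' @param rho optional equicorrelation among the simulated feature columns
#'   (default 0: independent columns).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param discretize if `TRUE`, the continuous phenotype is binned into four
#'   levels and replaced by `log(1..4)`, mimicking a log ordinal stage.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n, k, mains = NULL, pairs = NULL, noise_sd = 1,
                            mu = 0, rho = 0, seed = 1L, discretize = FALSE) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 10L) stop("need n >= 10")
  if (k < 2L) stop("need k >= 2")
  stopifnot(noise_sd > 0, rho >= 0, rho < 1)
  if (is.null(mains)) {
    mains <- data.frame(feature = integer(0), beta = numeric(0))
  }
  mains <- data.frame(feature = as.integer(mains$feature),
                      beta = as.numeric(mains$beta))
  if (nrow(mains) && (any(mains$feature < 1L) || any(mains$feature > k) ||
                      anyDuplicated(mains$feature))) {
    stop("main-effect features must be distinct indices in 1..k")
  }
  if (is.null(pairs)) {
    pairs <- data.frame(feature_i = integer(0), feature_j = integer(0),
                        beta = numeric(0))
  }
  pairs <- data.frame(feature_i = as.integer(pairs$feature_i),
                      feature_j = as.integer(pairs$feature_j),
                      beta = as.numeric(pairs$beta))
  if (nrow(pairs)) {
    if (any(pairs$feature_i == pairs$feature_j)) {
      stop("a pair must involve two distinct features")
    }
    swap <- pairs$feature_i > pairs$feature_j
    tmp <- pairs$feature_i[swap]
    pairs$feature_i[swap] <- pairs$feature_j[swap]
    pairs$feature_j[swap] <- tmp
    if (any(pairs$feature_i < 1L) || any(pairs$feature_j > k)) {
      stop("pair indices out of range 1..k")
    }
    if (anyDuplicated(pairs[, c("feature_i", "feature_j")])) {
      stop("duplicate pair(s) in the truth specification")
    }
  }
  structure(list(n = n, k = k, mains = mains, pairs = pairs,
                 noise_sd = noise_sd, mu = mu, rho = rho,
                 seed = as.integer(seed), discretize = isTRUE(discretize)),
            class = "synthetic_truth")
}

# zero-padded default feature names
synthetic_feature_names <- function(k) {
  sprintf(paste0("f%0", max(3L, nchar(k)), "d"), seq_len(k))
}

#' Simulate a dataset from a planted truth
#'
#' Draws the feature matrix, normalizes each column onto standard-normal
#' quantiles, assembles the phenotype from the planted main and pairwise
#' product effects plus Gaussian noise, and returns everything with the truth
#' attached. Bitwise reproducible from `truth$seed`.
#'
#' @param truth a [synthetic_truth()].
#' @return List with `X` (n x k normalized matrix), `y` (named phenotype
#'   vector) and `truth`.
#' @export
simulate_dataset <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(truth$seed)
  n <- truth$n; k <- truth$k
  Z <- matrix(rnorm(n * k), n, k)
  if (truth$rho > 0) {
    shared <- rnorm(n)
    Z <- sqrt(truth$rho) * shared + sqrt(1 - truth$rho) * Z
  }
  feats <- synthetic_feature_names(k)
  samples <- sprintf(paste0("s%0", max(3L, nchar(n)), "d"), seq_len(n))
  dimnames(Z) <- list(samples, feats)
  tab <- expr_table(t(Z))
  X <- inverse_quantile_normalize(tab)
  y <- rep(truth$mu, n)
  if (nrow(truth$mains)) {
    y <- y + drop(X[, truth$mains$feature, drop = FALSE] %*% truth$mains$beta)
  }
  if (nrow(truth$pairs)) {
    for (r in seq_len(nrow(truth$pairs))) {
      y <- y + X[, truth$pairs$feature_i[r]] * X[, truth$pairs$feature_j[r]] *
        truth$pairs$beta[r]
    }
  }
  y <- y + rnorm(n, sd = truth$noise_sd)
  if (truth$discretize) {
    br <- quantile(y, probs = c(0, 0.25, 0.5, 0.75, 1))
    ord <- as.integer(cut(y, breaks = unique(br), include.lowest = TRUE))
    y <- log(ord)
  }
  names(y) <- samples
  list(X = X, y = y, truth = truth)
}

#' Score workflow output against the planted truth
#'
#' A planted main effect counts as recovered iff its feature appears in the
#' workflow's main-effect table; a planted pair iff its canonical key appears
#' in the epistasis table. Every other reported term is a false discovery.
#' `power = recovered / planted` per effect class;
#' `fdr = false discoveries / max(1, total discoveries)`.
#'
#' @param result an `eben_workflow` (or a list with `main` and `epistasis`
#'   data frames in the same schema).
#' @param truth the [synthetic_truth()] the data came from.
#' @return List of class `recovery_report`: `power_main`, `power_pairs`,
#'   `power`, `fdr`, discovery counts, and the per-term relative beta error
#'   on recovered terms (`beta_rel_err`, named).
#' @export
evaluate_recovery <- function(result, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  feats <- synthetic_feature_names(truth$k)
  true_main <- feats[truth$mains$feature]
  true_pair <- paste(feats[truth$pairs$feature_i],
                     feats[truth$pairs$feature_j], sep = ":")
  found_main <- as.character(result$main$feature_1)
  found_pair <- paste(result$epistasis$feature_1,
                      result$epistasis$feature_2, sep = ":")
  rec_main <- intersect(true_main, found_main)
  rec_pair <- intersect(true_pair, found_pair)
  n_disc <- length(found_main) + length(found_pair)
  n_false <- sum(!found_main %in% true_main) + sum(!found_pair %in% true_pair)
  err <- c(
    if (length(rec_main)) {
      est <- result$main$beta[match(rec_main, found_main)]
      tru <- truth$mains$beta[match(rec_main, true_main)]
      stats::setNames(abs(est - tru) / abs(tru), rec_main)
    },
    if (length(rec_pair)) {
      est <- result$epistasis$beta[match(rec_pair, found_pair)]
      tru <- truth$pairs$beta[match(rec_pair, true_pair)]
      stats::setNames(abs(est - tru) / abs(tru), rec_pair)
    }
  )
  structure(list(
    power_main = if (length(true_main)) length(rec_main) / length(true_main) else NA_real_,
    power_pairs = if (length(true_pair)) length(rec_pair) / length(true_pair) else NA_real_,
    power = if (length(true_main) + length(true_pair)) {
      (length(rec_main) + length(rec_pair)) /
        (length(true_main) + length(true_pair))
    } else NA_real_,
    fdr = n_false / max(1L, n_disc),
    n_discoveries = n_disc,
    n_false = n_false,
    n_recovered = length(rec_main) + length(rec_pair),
    beta_rel_err = err
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "recovery: power_main = %.3g, power_pairs = %.3g, fdr = %.3g (%d discoveries)\n",
    x$power_main, x$power_pairs, x$fdr, x$n_discoveries))
  if (length(x$beta_rel_err)) {
    cat(sprintf("  mean relative beta error on recovered terms: %.3g\n",
                mean(x$beta_rel_err)))
  }
  invisible(x)
}
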