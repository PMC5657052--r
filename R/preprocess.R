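# Preprocessing: raw feature-expression tables and clinical stage labels are
# turned into the normalized samples-x-features design matrix and the
# log-transformed ordinal phenotype the workflow consumes.

#' Raw expression table
#'
#' A features-by-samples numeric matrix with explicit `NA` markers for missing
#' cells, plus unique feature and sample identifiers.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids identifiers; default to the dimnames.
#' @return An object of class `expr_table`.
#' @export
expr_table <- function(values, feature_ids = rownames(values),
                       sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids) || ncol(values) != length(sample_ids)) {
    stop("matrix dimensions do not match the identifier lists")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature identifier(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(feature_ids = feature_ids, sample_ids = sample_ids,
                 values = values),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expression table: %d features x %d samples (%.1f%% missing)\n",
              length(x$feature_ids), length(x$sample_ids),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Drop features with too much missing data
#'
#' Retains exactly the features whose fraction of missing cells is at most
#' `max_missing_frac`; features missing in strictly more than that fraction of
#' samples are dropped. The sample set and the original feature order are
#' unchanged. Idempotent.
#'
#' @param table an [expr_table()].
#' @param max_missing_frac maximum tolerated missing fraction (default 0.2,
#'   i.e. drop features with more than 20 percent missing data).
#' @return The filtered `expr_table`.
#' @export
filter_features_by_missingness <- function(table, max_missing_frac = 0.2) {
  stopifnot(inherits(table, "expr_table"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(table$values))
  keep <- frac <= max_missing_frac
  if (!any(keep)) {
    stop(sprintf("no features retained at missingness threshold %.3f",
                 max_missing_frac))
  }
  expr_table(table$values[keep, , drop = FALSE],
             table$feature_ids[keep], table$sample_ids)
}

#' Median-impute residual missing cells
#'
#' Replaces every missing cell by the median of its feature's observed values.
#' Imputation runs before rank normalization, so imputed cells share the
#' median's (average) rank.
#'
#' @param table an [expr_table()].
#' @return An `expr_table` with no missing values.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "expr_table"))
  v <- table$values
  all_missing <- rowSums(!is.na(v)) == 0L
  if (any(all_missing)) {
    stop("feature(s) with all values missing: ",
         paste(table$feature_ids[all_missing], collapse = ", "))
  }
  miss <- which(is.na(v), arr.ind = TRUE)
  if (nrow(miss)) {
    med <- apply(v, 1L, median, na.rm = TRUE)
    v[miss] <- med[miss[, 1L]]
  }
  expr_table(v, table$feature_ids, table$sample_ids)
}

#' Inverse quantile normalization
#'
#' Maps each feature's values onto standard-normal quantiles: within a
#' feature, value with rank `r` (average rank for ties) among `n` samples
#' becomes `qnorm(r / (n + 1))`. The result is transposed to samples x
#' features, the orientation the regression model consumes. A constant
#' feature maps to an all-zero column with a warning (all its average ranks
#' are `(n+1)/2`).
#'
#' @param table an [expr_table()] with no missing values (run
#'   [impute_missing()] first) and at least 3 samples.
#' @return Numeric matrix, samples in rows and features in columns, with the
#'   identifiers as dimnames.
#' @export
inverse_quantile_normalize <- function(table) {
  stopifnot(inherits(table, "expr_table"))
  if (anyNA(table$values)) {
    stop("missing values present; run impute_missing() first")
  }
  n <- length(table$sample_ids)
  if (n < 3L) stop("need at least 3 samples to quantile-normalize")
  constant <- apply(table$values, 1L, function(row) length(unique(row)) == 1L)
  if (any(constant)) {
    warning("constant feature(s) mapped to zero: ",
            paste(table$feature_ids[constant], collapse = ", "))
  }
  Z <- vapply(seq_along(table$feature_ids), function(i) {
    qnorm(rank(table$values[i, ], ties.method = "average") / (n + 1))
  }, numeric(n))
  dim(Z) <- c(n, length(table$feature_ids))
  dimnames(Z) <- list(table$sample_ids, table$feature_ids)
  Z
}

.stage_map <- c(I = 1L, II = 2L, III = 3L, IV = 4L)

#' Encode pathological stage labels as a log-ordinal phenotype
#'
#' Parses TCGA-style stage labels ("Stage I" ... "Stage IVB"), strips substage
#' suffixes (A/B/C collapse to the parent stage), maps the Roman numeral to an
#' ordinal 1..4 and sets the phenotype to its natural log. Samples with
#' unmappable labels are excluded and reported in the `"excluded"` attribute.
#'
#' @param clinical data frame with columns `sample_id` and `stage_label` (a
#'   two-column data frame in that order also works).
#' @return Data frame with columns `sample_id`, `stage_label`, `ordinal`,
#'   `y = log(ordinal)`; excluded samples (with reasons) in
#'   `attr(, "excluded")`.
#' @export
encode_stage_phenotype <- function(clinical) {
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "stage_label") %in% names(clinical))) {
    if (ncol(clinical) < 2L) stop("clinical input needs sample_id and stage_label")
    names(clinical)[1:2] <- c("sample_id", "stage_label")
  }
  lab <- toupper(trimws(as.character(clinical$stage_label)))
  m <- regmatches(lab, regexec("^STAGE[[:space:]]+([IVX]+)[ABC]?$", lab))
  roman <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                  character(1))
  ordinal <- unname(.stage_map[roman])
  ok <- !is.na(ordinal)
  excluded <- data.frame(sample_id = as.character(clinical$sample_id[!ok]),
                         stage_label = as.character(clinical$stage_label[!ok]),
                         reason = rep("unmappable stage label", sum(!ok)),
                         stringsAsFactors = FALSE)
  if (!any(ok)) stop("no samples with mappable stage labels")
  out <- data.frame(sample_id = as.character(clinical$sample_id[ok]),
                    stage_label = as.character(clinical$stage_label[ok]),
                    ordinal = ordinal[ok],
                    y = log(ordinal[ok]),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Align the normalized matrix and the phenotype on shared samples
#'
#' Restricts both inputs to their common samples, in the row order of the
#' expression matrix, and asserts the resulting sample sequences are
#' identical. Must run before any fit.
#'
#' @param X samples-by-features matrix with sample IDs as rownames.
#' @param phenotype output of [encode_stage_phenotype()] (or any data frame
#'   with `sample_id` and `y`).
#' @return List with the aligned `X`, `phenotype`, and named phenotype vector
#'   `y`.
#' @export
align_samples <- function(X, phenotype) {
  stopifnot(is.matrix(X), !is.null(rownames(X)),
            all(c("sample_id", "y") %in% names(phenotype)))
  common <- intersect(rownames(X), phenotype$sample_id)
  if (!length(common)) stop("no samples shared between expression and phenotype")
  X2 <- X[common, , drop = FALSE]
  ph2 <- phenotype[match(common, phenotype$sample_id), , drop = FALSE]
  rownames(ph2) <- NULL
  stopifnot(identical(rownames(X2), ph2$sample_id))
  list(X = X2, phenotype = ph2, y = stats::setNames(ph2$y, ph2$sample_id))
}

#' Full preprocessing pipeline
#'
#' Missingness filter, median imputation, inverse quantile normalization,
#' stage encoding and sample alignment in one call.
#'
#' @param table raw [expr_table()].
#' @param clinical clinical data frame (`sample_id`, `stage_label`).
#' @param max_missing_frac missingness threshold for
#'   [filter_features_by_missingness()].
#' @return List with `X` (normalized samples x features), `phenotype`, `y`,
#'   and `excluded` (samples dropped during stage encoding).
#' @export
preprocess_data <- function(table, clinical, max_missing_frac = 0.2) {
  tab <- filter_features_by_missingness(table, max_missing_frac)
  tab <- impute_missing(tab)
  X <- inverse_quantile_normalize(tab)
  ph <- encode_stage_phenotype(clinical)
  out <- align_samples(X, ph)
  out$excluded <- attr(ph, "excluded")
  out
}
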