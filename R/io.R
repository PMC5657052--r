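# TSV readers/writers (tab-delimited, UTF-8, Unix newlines) and results
# serialization. Expression tables follow the miRNASeq-matrix dialect: first
# column = feature ID, header row = sample IDs, empty/"NA"/"na"/"NaN" cells
# mark missing data.

.na_strings <- c("", "NA", "na", "NaN")

check_rectangular <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "",
                     blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged TSV: line ", bad, " of ", path, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
}

#' Read an expression TSV
#'
#' @param path TSV file: first column feature IDs, header row sample IDs,
#'   numeric cells with ""/"NA"/"na"/"NaN" as missing markers.
#' @return An [expr_table()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_rectangular(path)
  dt <- data.table::fread(path, sep = "\t", na.strings = .na_strings,
                          header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("expression TSV needs a feature column and >= 1 sample")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  expr_table(vals, feature_ids = ids, sample_ids = colnames(dt)[-1L])
}

#' Write an expression TSV
#'
#' Inverse of [read_expression_tsv()]; missing cells are written as "NA".
#'
#' @param table an [expr_table()].
#' @param path output file.
#' @export
write_expression_tsv <- function(table, path) {
  stopifnot(inherits(table, "expr_table"))
  df <- data.frame(feature_id = table$feature_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a clinical TSV
#'
#' Requires columns `sample_id` and `pathologic_stage` (case-insensitive);
#' extra columns are ignored and row order is preserved.
#'
#' @param path TSV file.
#' @return Data frame with `sample_id` and `stage_label`.
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = "character")
  low <- tolower(names(dt))
  i_id <- match("sample_id", low)
  i_st <- match("pathologic_stage", low)
  if (is.na(i_id) || is.na(i_st)) {
    stop("clinical TSV must contain columns 'sample_id' and ",
         "'pathologic_stage'; found: ", paste(names(dt), collapse = ", "))
  }
  data.frame(sample_id = dt[[i_id]], stage_label = dt[[i_st]],
             stringsAsFactors = FALSE)
}

#' Read/write a numeric phenotype TSV (`sample_id`, `y`)
#'
#' @param path TSV file.
#' @return Data frame with `sample_id` and `y`.
#' @export
read_phenotype_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  low <- tolower(names(dt))
  i_id <- match("sample_id", low)
  i_y <- match("y", low)
  if (is.na(i_id) || is.na(i_y)) {
    stop("phenotype TSV must contain columns 'sample_id' and 'y'; found: ",
         paste(names(dt), collapse = ", "))
  }
  data.frame(sample_id = as.character(dt[[i_id]]),
             y = as.numeric(dt[[i_y]]), stringsAsFactors = FALSE)
}

#' @rdname read_phenotype_tsv
#' @param phenotype data frame with `sample_id` and `y`.
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  data.table::fwrite(phenotype[, c("sample_id", "y")], path, sep = "\t",
                     quote = FALSE, eol = "\n")
  invisible(path)
}

# Table-1 style serialization: beta to 4 decimals, p in 6-significant-digit
# scientific notation.
format_result_table <- function(df) {
  out <- df
  for (col in intersect(c("beta", "se", "t"), names(out))) {
    out[[col]] <- sprintf("%.4f", out[[col]])
  }
  if ("p" %in% names(out)) out$p <- sprintf("%.6e", df$p)
  out
}

#' Write an EBEN fit as TSV
#'
#' Columns: `feature_key`, `beta`, `se`, `t`, `p`, `significant`.
#'
#' @param fit an `eben_fit`.
#' @param path output file.
#' @export
write_fit_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "eben_fit"))
  df <- fit$coefficients
  out <- data.frame(feature_key = df$feature,
                    format_result_table(df[, c("beta", "se", "t", "p")]),
                    significant = df$significant, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write workflow results
#'
#' Writes `unified_model.tsv` (effect_type, feature_1, feature_2 -- empty for
#' main effects --, beta, se, t, p), `main_effects.tsv`, `epistasis.tsv`,
#' `edges.tsv` (the epistatic rows only: feature_1, feature_2, beta, p, for
#' network import) and `provenance.json` (seed, per-step chosen
#' hyperparameters, package version). Re-running with an identical
#' configuration overwrites deterministically.
#'
#' @param result an `eben_workflow`.
#' @param out_dir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "eben_workflow"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    data.table::fwrite(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, eol = "\n")
  }
  uni <- result$unified
  wr(cbind(uni["effect_type"], uni[c("feature_1", "feature_2")],
           format_result_table(uni[, c("beta", "se", "t", "p")])),
     "unified_model.tsv")
  wr(cbind(result$main[c("feature_1", "feature_2")],
           format_result_table(result$main[, c("beta", "se", "t", "p")])),
     "main_effects.tsv")
  wr(cbind(result$epistasis[c("feature_1", "feature_2")],
           format_result_table(result$epistasis[, c("beta", "se", "t", "p")])),
     "epistasis.tsv")
  edges <- result$epistasis[, c("feature_1", "feature_2", "beta", "p")]
  edges$beta <- sprintf("%.4f", result$epistasis$beta)
  edges$p <- sprintf("%.6e", result$epistasis$p)
  wr(edges, "edges.tsv")
  prov <- list(
    package = "ebenepi",
    version = as.character(packageVersion("ebenepi")),
    seed = result$seed,
    alpha_level = result$alpha_level,
    folds = result$steps$folds,
    block = result$steps$block,
    fdr = result$steps$fdr,
    step1 = result$steps$step1[c("lambda1", "lambda2")],
    step3 = result$steps$step3[c("lambda1", "lambda2")],
    step4 = result$steps$step4[c("lambda1", "lambda2")]
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read back workflow result tables
#'
#' Parses the files produced by [write_results()].
#'
#' @param out_dir directory written by [write_results()].
#' @return List with `unified`, `main`, `epistasis`, `edges` data frames and
#'   the provenance list.
#' @export
read_results <- function(out_dir) {
  rd <- function(file) {
    data.table::fread(file.path(out_dir, file), sep = "\t",
                      data.table = FALSE)
  }
  list(unified = rd("unified_model.tsv"),
       main = rd("main_effects.tsv"),
       epistasis = rd("epistasis.tsv"),
       edges = rd("edges.tsv"),
       provenance = jsonlite::read_json(file.path(out_dir, "provenance.json")))
}
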