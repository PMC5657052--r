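Package: ebenepi
Title: Empirical Bayesian Elastic Net for Main and Epistatic Effects on
    Quantitative Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse Bayesian regression for detecting main and pairwise
    epistatic effects of molecular features (such as miRNA expression) on a
    quantitative or ordinal phenotype. Implements the empirical Bayesian
    elastic net (EBEN): greedy coordinate-ascent feature selection on the
    marginal log-posterior of per-coefficient precisions, with posterior
    t-tests on selected coefficients and cross-validated hyperparameter
    selection. Provides the four-step analysis workflow (main-effect scan,
    phenotype correction, exhaustive pairwise interaction scan on the
    corrected phenotype, unified re-estimation), rank-based inverse quantile
    normalization and clinical-stage preprocessing, a synthetic-data
    generator with planted effects for validation, TSV readers and writers,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
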