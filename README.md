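# ebenepi

Detection of main and pairwise epistatic effects of molecular features (e.g.
miRNA expression) on a quantitative or ordinal phenotype (e.g. tumor
pathological stage), using an **empirical Bayesian elastic net (EBEN)** —
a sparse Bayesian regression fitted by greedy coordinate ascent with
posterior *t*-tests on the selected coefficients — wrapped in a four-step
workflow designed to keep strong main effects from masking epistatic
signals.

## Who this is for

Analysts with a normalized feature matrix (samples × features) and a
per-sample phenotype who want a *tested* shortlist of individual features
and feature pairs associated with the phenotype, with effect sizes, standard
errors and p-values — not just the non-zero coefficients a lasso/elastic-net
point estimate returns.

## The model and method

The full model is

```
y = mu + X * beta_m + (X_i ∘ X_j) * beta_e + e,     e ~ N(0, sigma^2)
```

with `X` the inverse-quantile-normalized expression matrix, `beta_m` main
effects and `beta_e` pairwise (elementwise-product) epistatic effects. EBEN
gives each coefficient a two-level prior (normal × generalized-Gamma) whose
hyperparameters `(lambda1, lambda2)` mimic the elastic-net penalty, and
climbs the marginal log-posterior in the per-coefficient precisions
`alpha_k`:

```
L(alpha) = 1/2 [ log(alpha/(alpha+1+s)) + q^2/(alpha+1+s) ] - lambda2/alpha
```

A feature can enter only when `q^2 - s > lambda1 + 2*lambda2` (strictly);
otherwise its precision is infinite and its coefficient exactly zero.
Hyperparameters are chosen by 5-fold cross-validation over a data-scaled
grid. The workflow then runs in four steps: (1) main-effect scan on `y`;
(2) corrected phenotype `y' = y - X'_m beta'_m` over the significant mains;
(3) exhaustive pairwise interaction scan on `y'` (product columns streamed
in blocks); (4) unified re-estimation of all selected terms against the
original `y`, reporting only terms significant in the joint model. See the
methods vignette (`vignettes/eben-epistasis-methods.Rmd`) for the details
and design rationale.

## Worked example

```r
library(ebenepi)

truth <- synthetic_truth(
  n = 300, k = 30,
  mains = data.frame(feature = c(3, 11, 22), beta = 0.8),
  pairs = data.frame(feature_i = c(5, 9), feature_j = c(17, 25), beta = 0.6),
  noise_sd = 1, seed = 101)
sim <- simulate_dataset(truth)

wf <- run_workflow(sim$X, sim$y, seed = 101)
wf
```

prints

```
EBEN epistasis workflow result
  3 main effect(s), 2 epistatic pair(s) at p < 0.05
  effect_type feature_1 feature_2   beta      se      t         p
1        main      f011           0.7483 0.05671 13.195 1.534e-31
2        main      f003           0.6738 0.05625 11.980 3.375e-27
3        main      f022           0.5857 0.05588 10.482 4.743e-22
4   epistatic      f005      f017 0.6363 0.05314 11.975 3.514e-27
5   epistatic      f009      f025 0.5413 0.05588  9.686 1.944e-19
```

All five planted terms are recovered with no false discoveries: the three
main effects (true `beta = 0.8`) and both pairs (true `beta_e = 0.6`), each
with its posterior standard error, *t* statistic and two-sided p-value from
the unified Step-4 model. `evaluate_recovery(wf, truth)` scores this against
the planted truth (power, FDR, relative beta error).

Real data enter through the preprocessing pipeline:

```r
tab  <- read_expression_tsv("mirna_expression.tsv")   # features x samples
clin <- read_clinical_tsv("clinical.tsv")             # sample_id, pathologic_stage
pre  <- preprocess_data(tab, clin)                    # filter, impute, normalize, ln-stage
wf   <- run_workflow(pre$X, pre$y, seed = 1)
write_results(wf, "results/")
```

A command-line interface with `preprocess`, `fit`, `workflow`, `simulate`
and `evaluate` subcommands is available via `inst/cli/ebenepi.R` (or
`eben_cli()` from R); try
`Rscript inst/cli/ebenepi.R workflow --help`.

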