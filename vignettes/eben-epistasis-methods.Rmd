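---
title: "Detecting main and epistatic miRNA effects with the empirical Bayesian elastic net"
author: "ebenepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting main and epistatic miRNA effects with the empirical Bayesian elastic net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebenepi)
```

## The problem

Tumor progression phenotypes such as AJCC pathological stage are rarely
explained by individual molecular features alone. Pairwise *epistatic*
interactions — phenotypic variance explained by the joint (product) effect of
two features beyond their individual contributions — are biologically
plausible for miRNAs, which co-regulate shared target genes, but they are
statistically awkward: with $k$ features there are $k(k-1)/2$ candidate
pairs, and strong main effects can mask weaker interaction signals when
everything competes inside one regression.

`ebenepi` addresses both problems for a quantitative (or log-ordinal)
phenotype $y$ measured on $n$ samples with a normalized feature matrix
$X \in \mathbb{R}^{n \times k}$, under the linear model

$$ y = \mu + X\beta_m + X_i X_j \beta_e + e, \qquad e \sim N(0, \sigma^2), $$

where $X_i X_j$ denotes the elementwise product of two feature columns,
$\beta_m$ are main effects and $\beta_e$ are pairwise epistatic effects.

## The EBEN solver

The workhorse is an empirical Bayesian elastic net (EBEN): a sparse Bayesian
regression with a two-level coefficient prior — normal on each $\beta_k$,
generalized-Gamma on its variance — whose two hyperparameters
$(\lambda_1, \lambda_2)$ mimic the elastic-net penalty. Writing
$\tilde\alpha_k$ for the (unitless) precision of $\beta_k$, the solver does
greedy coordinate ascent on the marginal log-posterior

$$ L(\tilde\alpha_k) = \tfrac12\left[\log\frac{\tilde\alpha_k}
   {\tilde\alpha_k + 1 + s_k} + \frac{q_k^2}{\tilde\alpha_k + 1 + s_k}\right]
   - \frac{\lambda_2}{\tilde\alpha_k}, $$

where $s_k$ ("sparsity") and $q_k$ ("quality") summarize how much candidate
$k$ overlaps with the current model and with the residual signal. A candidate
can hold a finite precision — i.e., a non-zero coefficient — only when the
inclusion gate

$$ q_k^2 - s_k > \lambda_1 + 2\lambda_2 $$

holds strictly; otherwise $\tilde\alpha_k^\ast = \infty$ and the feature is
pruned. Each iteration evaluates, for every candidate, the optimal precision
$\tilde\alpha_k^\ast$ and the ascent gain
$\Delta L = L(\tilde\alpha_k^\ast) - L(\tilde\alpha_k^{(n)})$, then applies
the single best add / re-estimate / delete action. Iteration stops when (i)
no finite precision is proposed, or the active set is stable and both (ii)
the largest per-feature change and (iii) the Euclidean norm of the change in
$\tilde\alpha$ fall below tolerance (both default $10^{-6}$; hard cap 1000
iterations). Selected coefficients are then tested with posterior *t*-tests:
$t = \beta_k / \mathrm{se}(\beta_k)$ with the standard error from the
posterior covariance diagonal and $n - |A| - 1$ degrees of freedom ($|A|$ =
active-set size; the intercept is absorbed in $\mu$).

### Initialization

Following the algorithm's standard start: $\mu = \bar y$,
$\tilde y = y - \mu$, $\sigma_0^2 = 0.1\,\tilde y^\top \tilde y / n$
(deliberately small so the first iterations are permissive), and the first
candidate is the feature with the largest $|x_i^\top \tilde y|$ (lowest index
on ties). The noise variance is re-estimated after every action with the
evidence-style update
$\sigma_0^2 \leftarrow \lVert \tilde y - X_A \beta_A \rVert^2 / (n - \sum_k \gamma_k)$,
$\gamma_k = 1 - \tilde\alpha_k (\Sigma/\sigma_0^2)_{kk}$, floored at
$10^{-12}$; a non-positive denominator keeps the previous value with a
warning.

### The scaled prior and why it matters

We place the coefficient prior on the noise scale,
$\beta_k \sim N(0, \sigma_0^2 / \tilde\alpha_k)$, and compute $s_k, q_k$ from
the $\sigma_0$-whitened marginal covariance:

$$ S_k = x_k^\top (I + X_A \tilde A^{-1} X_A^\top)^{-1} x_k, \qquad
   Q_k = x_k^\top (I + X_A \tilde A^{-1} X_A^\top)^{-1} \tilde y / \sigma_0, $$

deflated for in-model features
($s_k = \tilde\alpha_k S_k / (\tilde\alpha_k - S_k)$, likewise $q_k$). With
$\sigma_0^2 = 1$ these are exactly $x_k^\top C^{-1} x_k$ and
$x_k^\top C^{-1} \tilde y$ for the marginal covariance
$C = \sigma_0^2 I + X_A \tilde A^{-1} X_A^\top$. The reason for the scaled
prior is dimensional: the "+1" sitting next to $s_k$ in $L$ is only coherent
if $\tilde\alpha$, $s$ and $q$ are unitless, and this choice makes the whole
selection path exactly invariant to the measurement units of $y$ — rescaling
$y \to c\,y$ rescales every $\beta$ by $c$ and leaves the selected set,
$\tilde\alpha$, $t$ and $p$ values unchanged (a property the test suite
verifies to $10^{-8}$). The posterior over the active set is then
$\Sigma = \sigma_0^2 (\tilde A + X_A^\top X_A)^{-1}$,
$\beta_A = (\tilde A + X_A^\top X_A)^{-1} X_A^\top \tilde y$, which is also
the dense oracle the tests compare against.

### The optimal precision in closed form

Setting $dL/d\tilde\alpha = 0$ and clearing denominators gives an exact
quadratic for every $\lambda_2 \ge 0$:

$$ (1 + s - q^2 + 2\lambda_2)\,\alpha^2 + \big[(1+s)^2 + 4\lambda_2(1+s)\big]\,
   \alpha + 2\lambda_2 (1+s)^2 = 0 , $$

which has a single positive root — the maximizer — exactly when
$q^2 > 1 + s + 2\lambda_2$. With $\lambda_2 = 0$ it reduces to
$\alpha^\ast = (1+s)^2 / (q^2 - 1 - s)$; for example $s = 1, q^2 = 9$ gives
$\alpha^\ast = 4/7$. We use this closed form rather than a numeric 1-D
search: it is exact, satisfies the stationarity condition by construction,
and is vectorizable over tens of thousands of pair candidates (the test
suite cross-checks it against a numeric maximizer of $L$). Note a quirk of
the printed equations: the inclusion gate is $q^2 - s > \lambda_1 +
2\lambda_2$, but a finite interior maximum additionally needs
$q^2 > 1 + s + 2\lambda_2$. In the narrow band between the two, $L$
increases monotonically toward its pruned-state value and we return
$\tilde\alpha^\ast = \infty$ (prune) — the only self-consistent reading.

## Hyperparameter selection

$(\lambda_1, \lambda_2)$ are chosen by $k$-fold cross-validated prediction
error (5 folds by default, sample-wise simple random folds, deterministic in
the seed; no stratification — the phenotype has few levels and the model
treats it as continuous). The default grid is data-scaled: since the gate
statistic $q^2 - s$ grows with $n$ (it is roughly $n(z^2 - 1)$ for a
candidate with correlation z-score $z$ at the null noise scale), any fixed
$O(1)$ grid is inert. We anchor at
$\lambda_{\max} = \max_k (q_k^2 - s_k)$ evaluated at the empty model with
$\sigma_0^2 = \tilde y^\top \tilde y / n$ — the smallest gate that excludes
every candidate — and ladder down two decades in four geometric steps
($\lambda_{\max} \times \{1, 0.22, 0.046, 0.01\}$) for each hyperparameter
(16 grid points). Ratios much below $0.01$ admit a large fraction of pure
noise candidates; cross-validation rejects those models anyway, so the
ladder stops where a sparse model can still live. Ties in CV error break
toward the larger effective gate $\lambda_1 + 2\lambda_2$ (the sparser
model). Scoring fits run under an iteration budget
(`max_cv_iterations = 250`): grid points lax enough to admit huge noise
models are truncated — their held-out error is terrible either way, which is
all CV needs to know — while final fits at the chosen pair always run to
full convergence.

## The four-step workflow

Main effects that dominate the phenotype can mask epistatic signals in a
joint scan. The workflow therefore separates the two:

1. **Main-effect scan.** EBEN over the $k$ feature columns against $y$;
   features with $p < 0.05$ are the significant mains.
2. **Phenotype correction.** $y' = y - X'_m \beta'_m$ over the significant
   mains only ($\mu$ is not subtracted; the next fit re-estimates its own
   mean). With no significant mains, $y' = y$.
3. **Epistasis scan.** EBEN over all $k(k-1)/2$ centered product columns
   against $y'$ — main-effect columns are not candidates here. Product
   columns are generated block-wise (1000 at a time by default), so memory
   stays bounded by block size $\times\, n$ however many pairs are
   enumerated; products are centered by their own mean but never
   re-normalized, since the model is written in raw products.
4. **Unified model.** The Step-1 mains and Step-3 pairs are re-estimated
   jointly against the *original* $y$, with fresh cross-validation; only
   terms significant ($p < 0.05$) in this joint model are reported. The
   final table therefore re-prices every term: a main effect absorbed by a
   correlated pair (or vice versa) drops out here.

Each of Steps 1, 3 and 4 re-runs hyperparameter CV because the candidate
designs have very different dimensionality. Raw $p < 0.05$ per step is the
workflow's native rule; a Benjamini–Hochberg option (`fdr = TRUE`) exists
but is off by default. Pairs are always canonicalized to $(i, j)$ with
$i < j$, so no pair can appear twice under two orderings.

## Preprocessing

Expression tables arrive features $\times$ samples with explicit missing
markers. The pipeline: (1) drop features missing in **strictly more than**
20% of samples (a feature missing in exactly 20% is retained); (2)
median-impute the remaining missing cells per feature — imputation happens
before ranking, so imputed cells share the median's average rank; (3)
inverse quantile normalization, mapping each feature's rank $r$ (average
ranks for ties) among $n$ samples to $\Phi^{-1}(r/(n+1))$ — the simple
offset, strictly inside $(0,1)$; Blom-type offsets differ by $O(1/n)$ and
nothing here depends on the distinction; (4) transpose to samples $\times$
features. A constant feature maps to an all-zero column with a warning
rather than an error — downstream selection simply never picks it. Stage
labels ("Stage I" … "Stage IVB") are collapsed to their parent stage
(IIA $\to$ II), mapped to ordinals 1–4 and log-transformed,
$y = \ln(\text{ordinal})$; unmappable labels exclude the sample with a
logged reason. Expression and phenotype are then aligned on their shared
samples, in expression-row order, and the identity of the two ID sequences
is asserted before any fit.

## The synthetic-data generator

`synthetic_truth()` / `simulate_dataset()` draw $X$ i.i.d. standard normal
and pass each column through the same inverse-quantile map the real pipeline
applies (so marginals match the pipeline's inputs exactly), then assemble
$y$ from the planted mains, planted pair products and $N(0, \sigma^2)$
noise. Columns are independent by default; an equicorrelation parameter
$\rho$ stresses collinearity when wanted, and a discretize option bins $y$
into four levels and replaces it by $\ln\{1,2,3,4\}$ to mimic the log-stage
phenotype. What the generator does *not* emulate: the heavy-tailed count
origin of miRNASeq data (normalization erases it), realistic miRNA–miRNA
correlation structure, and confounders — so passing recovery tests
demonstrates correctness of the machinery under the model's own
assumptions, not robustness to everything real data can do.

The validation suite runs at desk scale, chosen so the full suite completes
in minutes on one CPU: 25-replicate recovery at $n = 300, k = 30$ (three
mains $\beta = 0.8$, two pairs $\beta_e = 0.6$, $\sigma = 1$), 25-replicate
null calibration at $n = 200, k = 30$, an anti-masking comparison at
$n = 300, k = 20$ against a single joint scan of all main + pair columns,
and a 50-instance dense-oracle equivalence check at $n \le 12, k \le 4$.
`scripts/acceptance.R` recomputes all of these from scratch.

## Numerical choices and degenerate inputs

* Ties in the greedy argmax (and in the initialization) break toward the
  lowest feature index — determinism over elegance.
* The active-set posterior and all $s/q$ caches are recomputed exactly from
  the current active set after every action (Cholesky on the $|A| \times
  |A|$ whitened Gram); only candidate cross-products are cached
  incrementally. Add-then-delete restores the previous state to machine
  precision.
* If an active feature's deflation denominator $\tilde\alpha_k - S_k$
  becomes non-positive (numerical degeneracy), the feature is marked
  gate-failing, which routes it to deletion rather than propagating NaNs.
* A constant phenotype, an all-missing feature, fewer than 3 samples for
  normalization, fewer than 10 samples for the workflow, and $df \le 0$ in
  the *t*-test are all explicit errors.
* Lost positive-definiteness of the posterior raises an error naming the
  active set.

## Worked example

```{r example, eval = FALSE}
truth <- synthetic_truth(
  n = 300, k = 30,
  mains = data.frame(feature = c(3, 11, 22), beta = 0.8),
  pairs = data.frame(feature_i = c(5, 9), feature_j = c(17, 25), beta = 0.6),
  noise_sd = 1, seed = 101)
sim <- simulate_dataset(truth)
wf <- run_workflow(sim$X, sim$y, seed = 101)
wf
evaluate_recovery(wf, truth)
```

## Known limitations

* Gaussian likelihood only; the ordinal stage is treated as continuous after
  the log transform (the model's own assumption).
* No covariate adjustment and no three-way or higher interactions.
* The Step-3 scan is exhaustive over pairs; at $k$ in the hundreds this is
  the compute bottleneck (the cross-validated search dominates, exactly as
  expected for this design).
* Raw per-step $p < 0.05$ without multiplicity correction is the workflow's
  native rule; with 70,500 candidate pairs this is lenient by construction,
  and the unified Step-4 refit is the main guard against spurious terms.
* The default $\lambda$ ladder is anchored to the strongest candidate; a
  signal more than two decades below it needs a user-supplied grid.
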