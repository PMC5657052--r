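# Shared fixtures, all built in code at test time.

# small raw expression table with controlled missingness
tiny_expr_table <- function() {
  v <- rbind(
    m1 = c(5, 1, 9, 2, 4),    # complete
    m2 = c(1, NA, 3, 4, 5),   # 20% missing (exactly at threshold)
    m3 = c(NA, NA, 7, 7, 7),  # 40% missing
    m4 = c(2, 2, 2, 2, 2)     # constant
  )
  colnames(v) <- paste0("s", 1:5)
  expr_table(v)
}

tiny_clinical <- function() {
  data.frame(
    sample_id = paste0("s", 1:6),
    stage_label = c("Stage I", "Stage IIA", "Stage III", "Stage IVB",
                    "Stage X", "stage ii"),
    stringsAsFactors = FALSE
  )
}

# deterministic planted-signal dataset at the scale used across tests
planted_sim <- function(seed, n = 300, k = 30,
                        mains = data.frame(feature = c(3, 11, 22), beta = 0.8),
                        pairs = data.frame(feature_i = c(5, 9),
                                           feature_j = c(17, 25), beta = 0.6),
                        noise_sd = 1) {
  simulate_dataset(synthetic_truth(n, k, mains = mains, pairs = pairs,
                                   noise_sd = noise_sd, seed = seed))
}

# dense Bayesian linear-regression oracle: posterior mean of beta given the
# converged precisions and the prior beta_k ~ N(0, sigma0^2/alpha_k)
dense_posterior_oracle <- function(X, y, fit) {
  Xa <- X[, fit$active, drop = FALSE]
  drop(solve(diag(unname(fit$alpha), length(fit$active)) + crossprod(Xa),
             crossprod(Xa, y - fit$mu)))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
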