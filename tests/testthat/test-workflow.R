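test_that("pair enumeration is canonical, lexicographic and complete", {
  p3 <- enumerate_interactions(3)
  expect_identical(unname(p3), cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)))
  expect_identical(nrow(enumerate_interactions(2)), 1L)
  expect_identical(nrow(enumerate_interactions(376)), 70500L)
  expect_true(all(enumerate_interactions(20)[, 1] <
                    enumerate_interactions(20)[, 2]))
  expect_error(enumerate_interactions(1), "2")
})

test_that("interaction columns are centered products, identical in blocks", {
  X <- cbind(a = c(1, 2), b = c(3, 4))
  expect_equal(build_interaction_column(X, 1, 2), c(-2.5, 2.5))
  Xz <- cbind(a = c(1, 2, 3), b = c(0, 0, 0))
  expect_identical(build_interaction_column(Xz, 1, 2), c(0, 0, 0))
  # the column built alone equals the one streamed from a (tiny) block design
  set.seed(41)
  Xr <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  d <- interaction_design(Xr, block = 3L)
  pairs <- enumerate_interactions(5)
  for (r in c(1L, 4L, 10L)) {
    expect_equal(drop(ebenepi:::design_cols(d, r)),
                 build_interaction_column(Xr, pairs[r, 1], pairs[r, 2]))
  }
  # block size must not change cross-products either
  d1 <- interaction_design(Xr, block = 1L)
  v <- rnorm(12)
  expect_equal(ebenepi:::design_cross_vec(d, v),
               ebenepi:::design_cross_vec(d1, v))
})

test_that("phenotype correction subtracts significant main effects only", {
  X <- cbind(f1 = c(1, 2), f2 = c(5, 1))
  fit <- structure(list(coefficients = data.frame(
    feature = c("f1", "f2"), beta = c(0.5, 9), se = 1, t = 1,
    p = c(0.01, 0.9), significant = c(TRUE, FALSE),
    stringsAsFactors = FALSE)), class = "eben_fit")
  corr <- correct_phenotype(c(3, 4), X, fit)
  expect_equal(unname(corr$y_prime), c(2.5, 3))
  expect_identical(corr$removed$feature, "f1")
  # empty significant set leaves y unchanged
  fit0 <- fit
  fit0$coefficients$significant <- FALSE
  expect_equal(unname(correct_phenotype(c(3, 4), X, fit0)$y_prime), c(3, 4))
  # correcting with beta then with -beta restores y exactly
  fit_neg <- fit
  fit_neg$coefficients$beta <- -fit$coefficients$beta
  twice <- correct_phenotype(corr$y_prime, X, fit_neg)
  expect_equal(unname(twice$y_prime), c(3, 4))
  # unknown features are an error
  fit_bad <- fit
  fit_bad$coefficients$feature <- c("zz", "f2")
  expect_error(correct_phenotype(c(3, 4), X, fit_bad), "zz")
})

test_that("main-effect scan flags a planted effect and little else", {
  sim <- planted_sim(71, n = 200, k = 10,
                     mains = data.frame(feature = 4, beta = 1), pairs = NULL)
  fit <- scan_main_effects(sim$X, sim$y, seed = 71)
  sig <- fit$coefficients[fit$coefficients$significant, ]
  expect_true("f004" %in% sig$feature)
  expect_lte(nrow(sig), 3)
})

test_that("epistasis scan on the corrected phenotype finds a planted pair", {
  sim <- planted_sim(72, n = 300, k = 20, mains = NULL,
                     pairs = data.frame(feature_i = 3, feature_j = 7,
                                        beta = 0.8))
  fit <- scan_epistasis(sim$X, sim$y, seed = 72)
  sig <- fit$coefficients[fit$coefficients$significant, ]
  expect_true("f003:f007" %in% sig$feature)
})

test_that("an empty combined selection yields an empty result with warning", {
  expect_warning(res <- fit_unified_model(matrix(rnorm(40), 20, 2),
                                          character(0), NULL, rnorm(20)),
                 "empty")
  expect_identical(nrow(res$unified), 0L)
  expect_identical(nrow(res$main), 0L)
  expect_identical(nrow(res$epistasis), 0L)
})

test_that("with no significant mains, later steps see the original phenotype", {
  sim <- planted_sim(73, n = 120, k = 8, mains = NULL,
                     pairs = data.frame(feature_i = 2, feature_j = 6,
                                        beta = 1.2))
  wf <- suppressWarnings(run_workflow(sim$X, sim$y, seed = 73))
  # Step 2 identity: no mains removed
  expect_identical(nrow(wf$steps$step2$removed), 0L)
  expect_true("f002" %in% wf$epistasis$feature_1 &
                "f006" %in% wf$epistasis$feature_2)
})

test_that("the full workflow recovers planted mains and pairs canonically", {
  sim <- planted_sim(74)
  wf <- run_workflow(sim$X, sim$y, seed = 74)
  expect_true(all(c("f003", "f011", "f022") %in% wf$main$feature_1))
  keys <- paste(wf$epistasis$feature_1, wf$epistasis$feature_2, sep = ":")
  expect_true(all(c("f005:f017", "f009:f025") %in% keys))
  # canonical pairs only: (i,j) and (j,i) never both present
  rev_keys <- paste(wf$epistasis$feature_2, wf$epistasis$feature_1, sep = ":")
  expect_length(intersect(keys, rev_keys), 0)
  # every reported row passed the step-4 filter
  expect_true(all(wf$unified$p < wf$alpha_level))
  # provenance carries the per-step penalties
  expect_true(is.finite(wf$steps$step1$lambda1))
  expect_true(is.finite(wf$steps$step3$lambda1))
})

test_that("workflow results are invariant to feature order up to relabeling", {
  sim <- planted_sim(75, n = 150, k = 10,
                     mains = data.frame(feature = 2, beta = 1),
                     pairs = data.frame(feature_i = 4, feature_j = 9,
                                        beta = 0.9))
  wf1 <- suppressWarnings(run_workflow(sim$X, sim$y, seed = 75))
  perm <- rev(seq_len(ncol(sim$X)))
  wf2 <- suppressWarnings(run_workflow(sim$X[, perm], sim$y, seed = 75))
  expect_setequal(wf1$main$feature_1, wf2$main$feature_1)
  k1 <- apply(wf1$epistasis[, 1:2], 1, function(r) paste(sort(r), collapse = ":"))
  k2 <- apply(wf2$epistasis[, 1:2], 1, function(r) paste(sort(r), collapse = ":"))
  expect_setequal(k1, k2)
})

test_that("the workflow refuses degenerate inputs", {
  X <- matrix(rnorm(8 * 3), 8, 3)
  expect_error(run_workflow(X, rnorm(8)), "10 samples")
})
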