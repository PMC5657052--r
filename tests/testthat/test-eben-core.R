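test_that("marginal log-posterior matches direct evaluation", {
  # L(1; s=1, q^2=9, l2=0) = (log(1/3) + 3)/2
  expect_equal(log_posterior_alpha(1, 1, 3, 0), 0.5 * (log(1 / 3) + 3),
               tolerance = 1e-12)
  expect_equal(log_posterior_alpha(1, 1, 3, 0.5),
               0.5 * (log(1 / 3) + 3) - 0.5, tolerance = 1e-12)
  expect_identical(log_posterior_alpha(Inf, 1, 3, 0), 0)
  # L -> 0 as alpha -> Inf for lambda2 = 0
  expect_lt(abs(log_posterior_alpha(1e12, 1, 3, 0)), 1e-10)
  expect_error(log_posterior_alpha(0, 1, 3), "positive")
  expect_error(log_posterior_alpha(-1, 1, 3), "positive")
})

test_that("optimal precision agrees with the numeric maximizer of L", {
  # closed form at lambda2 = 0: (1+s)^2 / (q^2 - 1 - s)
  expect_equal(optimal_alpha(1, 3, 0, 0), 4 / 7, tolerance = 1e-10)
  set.seed(11)
  for (r in 1:20) {
    s <- runif(1, 0, 5)
    q <- runif(1, sqrt(1 + s) + 0.3, 6 + s)
    l2 <- sample(c(0, 0.05, 0.4), 1)
    a <- optimal_alpha(s, q, 0, l2)
    if (is.finite(a)) {
      num <- optimize(function(al) log_posterior_alpha(al, s, q, l2),
                      interval = c(1e-8, 1e8), maximum = TRUE,
                      tol = 1e-12)$maximum
      expect_equal(a, num, tolerance = 1e-6)
      # stationarity of L at the returned value
      h <- 1e-5 * a
      expect_lt(abs(log_posterior_alpha(a + h, s, q, l2) -
                    log_posterior_alpha(a - h, s, q, l2)) / (2 * h), 1e-6)
    }
  }
})

test_that("the inclusion gate is strict and prunes otherwise", {
  # boundary: q^2 - s == lambda1 + 2*lambda2 exactly -> pruned
  expect_identical(optimal_alpha(1, 3, 8, 0), Inf)
  expect_identical(optimal_alpha(1, 3, 4, 2), Inf)
  # q = 0 can never pass for any lambda >= 0
  expect_identical(optimal_alpha(2, 0, 0, 0), Inf)
  # gate passes but no finite interior maximum (q^2 <= 1 + s + 2*lambda2)
  expect_identical(optimal_alpha(1, sqrt(1.5), 0, 0), Inf)
  # vectorized
  expect_identical(optimal_alpha(c(1, 2), c(3, 0)), c(4 / 7, Inf))
})

test_that("initialization follows the stated formulas", {
  X <- matrix(rnorm(8), 4, 2)
  st <- ebenepi:::eben_init_state(main_effect_design(X), c(0, 1, 2, 3))
  expect_equal(st$mu, 1.5)
  expect_equal(st$yt, c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(st$sigma0_sq, 0.1 * 5 / 4)

  # initial candidate has the largest |x' ytilde|
  X2 <- cbind(a = c(1, 0, 0, 0) * 3, b = c(-5, 0, 0, 0))
  yt <- c(1, -1 / 3, -1 / 3, -1 / 3) # mean zero; x1'yt = 3, x2'yt = -5
  st2 <- ebenepi:::eben_init_state(main_effect_design(X2), yt)
  expect_equal(st2$mu, 0)
  expect_equal(st2$yt, yt)
  expect_identical(st2$init_feature, 2L)

  expect_error(ebenepi:::eben_init_state(main_effect_design(X),
                                         rep(2, 4)), "constant")
})

test_that("s/q statistics reduce to raw moments at the empty model", {
  # x'x = 4, x'ytilde = 2, sigma0^2 = 1 -> s = 4, q = 2
  X <- cbind(f = c(1, 1, -1, -1))
  y <- c(1, 1, 0, 0)
  st <- ebenepi:::eben_init_state(main_effect_design(X), y)
  st$sigma0_sq <- 1
  st <- ebenepi:::eben_refresh(st)
  expect_equal(unname(ebenepi:::compute_sq(st, 1)), c(4, 2))
})

test_that("exactly orthogonal candidates are unaffected by other updates", {
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(20 * 4), 20, 4)))
  y <- rnorm(20)
  st <- ebenepi:::eben_init_state(main_effect_design(Q), y)
  before <- c(st$s[3], st$q[3])
  st2 <- ebenepi:::apply_update(st, list(type = "add", feature = 1L,
                                         alpha = 2.5, delta_L = 1))
  expect_equal(c(st2$s[3], st2$q[3]), before, tolerance = 1e-12)
})

test_that("greedy selection picks the largest gain and classifies actions", {
  set.seed(22)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- 1.2 * X[, 2] + 0.4 * X[, 4] + rnorm(60, sd = 0.5)
  st <- ebenepi:::eben_init_state(main_effect_design(X), y)
  act <- ebenepi:::select_update(st)
  expect_identical(act$type, "add")
  # the chosen action must attain the maximal positive gain over candidates
  astar <- optimal_alpha(st$s, st$q, 0, 0)
  gains <- ifelse(is.finite(astar),
                  log_posterior_alpha(astar, st$s, st$q, 0), -Inf)
  expect_identical(act$feature, which.max(gains))
  expect_equal(act$delta_L, max(gains))

  # a no-op is returned when nothing can improve (everything gated out)
  st_gated <- ebenepi:::eben_init_state(main_effect_design(X), y,
                                        lambda1 = 1e9)
  expect_identical(ebenepi:::select_update(st_gated)$type, "none")
})

test_that("add followed by delete restores the state; no-op is identity", {
  set.seed(23)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- rnorm(30)
  st <- ebenepi:::eben_init_state(main_effect_design(X), y)
  st2 <- ebenepi:::apply_update(st, list(type = "add", feature = 2L,
                                         alpha = 3, delta_L = 1))
  expect_identical(st2$active, 2L)
  st3 <- ebenepi:::apply_update(st2, list(type = "delete", feature = 2L))
  expect_equal(st3$s, st$s, tolerance = 1e-8)
  expect_equal(st3$q, st$q, tolerance = 1e-8)
  expect_identical(st3$active, integer(0))
  expect_identical(ebenepi:::apply_update(st, list(type = "none")), st)
})

test_that("added coefficients match the dense ridge-posterior oracle", {
  set.seed(24)
  for (r in 1:10) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rnorm(n)
    st <- ebenepi:::eben_init_state(main_effect_design(X), y)
    j <- st$init_feature
    a <- optimal_alpha(st$s[j], st$q[j])
    if (!is.finite(a)) next
    st2 <- ebenepi:::apply_update(st, list(type = "add", feature = j,
                                           alpha = a, delta_L = 1))
    oracle <- solve(a + sum(X[, j]^2), sum(X[, j] * st$yt))
    expect_equal(st2$beta, drop(oracle), tolerance = 1e-10)
  }
})

test_that("noise-variance update tracks the residual variance", {
  # planted signal: converged estimate within 20% of the true sigma^2 = 1
  sim <- planted_sim(42, n = 500, k = 10,
                     mains = data.frame(feature = c(1, 4, 8),
                                        beta = c(1, -0.8, 0.6)),
                     pairs = NULL)
  fit <- eben_fit(sim$X, sim$y)
  expect_lt(abs(fit$sigma0_sq - 1), 0.2)

  # empty active set leaves sigma0^2 untouched
  st <- ebenepi:::eben_init_state(main_effect_design(sim$X), sim$y)
  expect_identical(ebenepi:::update_noise_variance(st)$sigma0_sq,
                   st$sigma0_sq)
})

test_that("convergence criteria follow the three stated rules", {
  ctrl <- eben_control()
  a1 <- c("1" = 2, "5" = 3)
  expect_true(ebenepi:::check_convergence(a1, a1, TRUE, ctrl))
  # a change of 2x the tolerance on one alpha is not converged
  a2 <- a1 + c(2 * ctrl$alpha_change_tol, 0)
  expect_false(ebenepi:::check_convergence(a1, a2, TRUE, ctrl))
  # membership change is never converged under rules ii+iii
  expect_false(ebenepi:::check_convergence(a1, c(a1, "7" = 1), TRUE, ctrl))
  # rule i: no finite candidate proposed wins regardless of history
  expect_true(ebenepi:::check_convergence(a1, a2, FALSE, ctrl))
})

test_that("posterior t-tests use df = n - active - 1 and behave monotonically", {
  set.seed(25)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- X[, 1] - 0.8 * X[, 5] + rnorm(100, sd = 0.4)
  fit <- eben_fit(X, y)
  expect_identical(fit$df, 100L - length(fit$active) - 1L)
  co <- fit$coefficients
  expect_equal(co$t, co$beta / co$se)
  expect_equal(co$p, 2 * pt(-abs(co$t), fit$df))
  # doubling se halves |t| and increases p
  expect_true(all(2 * pt(-abs(co$t) / 2, fit$df) > co$p))
  # beta = 0 gives t = 0, p = 1
  expect_identical(2 * pt(-abs(0 / 1), fit$df), 1)
})

test_that("a perfect univariate fit selects its column with tiny residual", {
  set.seed(26)
  x <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "only"))
  fit <- eben_fit(x, drop(x))
  expect_identical(fit$coefficients$feature, "only")
  expect_lt(fit$sigma0_sq, 0.01 * var(drop(x)))
  expect_equal(fit$coefficients$beta, 1, tolerance = 0.01)
})

test_that("a planted single effect is recovered with beta within 10%", {
  set.seed(27)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- 2 * X[, 3] + rnorm(200, sd = 0.1)
  fit <- eben_fit(X, y)
  sig <- fit$coefficients[fit$coefficients$significant, ]
  expect_true("x3" %in% sig$feature)
  expect_lt(abs(sig$beta[sig$feature == "x3"] - 2) / 2, 0.10)
})

test_that("pure-noise responses rarely select features at moderate penalties", {
  false_sel <- vapply(1:25, function(s) {
    sim <- planted_sim(400 + s, n = 100, k = 20, mains = NULL, pairs = NULL)
    lad <- lambda_ladder(main_effect_design(sim$X), sim$y)
    fit <- suppressWarnings(eben_fit(sim$X, sim$y, lad[2], lad[2]))
    sum(fit$coefficients$significant)
  }, numeric(1))
  expect_lte(mean(false_sel), 1)
})

test_that("every applied action strictly increases the objective", {
  set.seed(28)
  for (r in 1:8) {
    n <- 40; k <- 6
    X <- matrix(rnorm(n * k), n, k)
    y <- X[, 1] * runif(1, 0.5, 2) + rnorm(n)
    fit <- eben_fit(X, y, lambda1 = 0.5, lambda2 = 0.5)
    expect_true(all(fit$diagnostics$delta_L > 0))
  }
})

test_that("converged precisions are stationary points of the objective", {
  set.seed(29)
  for (r in 1:10) {
    n <- sample(8:12, 1); k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n) + X[, 1]
    fit <- eben_fit(X, y)
    if (!length(fit$active)) next
    st <- ebenepi:::eben_init_state(main_effect_design(X), y)
    st$active <- fit$active
    st$alpha <- unname(fit$alpha)
    st$Xa <- X[, fit$active, drop = FALSE]
    st$B <- t(crossprod(X, st$Xa))
    st$sigma0_sq <- fit$sigma0_sq
    st <- ebenepi:::eben_refresh(st)
    astar <- optimal_alpha(st$s[fit$active], st$q[fit$active])
    rel <- abs(astar - st$alpha) / pmax(1, abs(astar))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("rescaling the phenotype rescales the coefficients exactly", {
  set.seed(30)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y <- 1.5 * X[, 2] + rnorm(60, sd = 0.5)
  f1 <- eben_fit(X, y)
  for (c0 in c(100, 1e-3)) {
    f2 <- eben_fit(X, c0 * y)
    expect_identical(f1$active, f2$active)
    expect_equal(f2$coefficients$beta, c0 * f1$coefficients$beta,
                 tolerance = 1e-8)
    expect_equal(f2$coefficients$p, f1$coefficients$p, tolerance = 1e-8)
  }
})

test_that("features failing the gate at every iteration never enter", {
  set.seed(31)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- rnorm(50)
  # a gate larger than any achievable q^2 - s excludes everything
  lad <- lambda_ladder(main_effect_design(X), y)
  fit <- eben_fit(X, y, lambda1 = 100 * max(lad), lambda2 = 100 * max(lad))
  expect_identical(fit$active, integer(0))
  expect_identical(nrow(fit$coefficients), 0L)
})

test_that("fits are deterministic in their inputs", {
  sim <- planted_sim(5, n = 60, k = 8,
                     mains = data.frame(feature = 2, beta = 1), pairs = NULL)
  f1 <- eben_fit(sim$X, sim$y, 1, 1)
  f2 <- eben_fit(sim$X, sim$y, 1, 1)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$sigma0_sq, f2$sigma0_sq)
})
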