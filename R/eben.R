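# Empirical Bayesian elastic net (EBEN) solver.
#
# Linear model y = mu + X beta + e, e ~ N(0, sigma0^2). Each coefficient has a
# two-level prior: beta_k ~ N(0, sigma0^2 / alpha_k) with a generalized-Gamma
# style hyperprior on the variance whose hyperparameters (lambda1, lambda2)
# mimic the elastic-net penalty. Features are selected by greedy coordinate
# ascent on the marginal log-posterior in alpha_k,
#
#   L(alpha) = 1/2 [ log(alpha / (alpha + 1 + s)) + q^2 / (alpha + 1 + s) ]
#              - lambda2 / alpha,
#
# where s_k, q_k are the sparsity/quality statistics of candidate k derived
# from the marginal covariance of the response. A feature can carry a finite
# alpha (and hence a non-zero coefficient) only when q^2 - s > lambda1 +
# 2*lambda2; all other features are pruned (alpha infinite, beta zero).
#
# Scaling the coefficient prior by sigma0^2 makes alpha, s and q unitless, so
# the selection path is invariant to the measurement units of y. Internally
# the statistics are therefore computed in the sigma0-whitened space:
#   S_k = x_k' (I + X_A A^-1 X_A')^-1 x_k
#   Q_k = x_k' (I + X_A A^-1 X_A')^-1 ytilde / sigma0
# with A = diag(alpha) over the active set; with sigma0^2 = 1 these are
# exactly x_k' C^-1 x_k and x_k' C^-1 ytilde for C = sigma0^2 I + X_A A^-1 X_A'.

#' Solver control parameters
#'
#' @param alpha_change_tol convergence tolerance on the largest per-feature
#'   change in alpha between iterations.
#' @param norm_change_tol convergence tolerance on the Euclidean norm of the
#'   change in alpha between iterations.
#' @param max_iterations iteration cap; the solver warns if it is reached.
#' @param p_threshold two-sided p-value below which a selected coefficient is
#'   flagged significant.
#' @return A list of class `eben_control`.
#' @export
eben_control <- function(alpha_change_tol = 1e-6, norm_change_tol = 1e-6,
                         max_iterations = 1000L, p_threshold = 0.05) {
  stopifnot(alpha_change_tol > 0, norm_change_tol > 0,
            max_iterations >= 1, p_threshold > 0, p_threshold < 1)
  structure(list(alpha_change_tol = alpha_change_tol,
                 norm_change_tol = norm_change_tol,
                 max_iterations = as.integer(max_iterations),
                 p_threshold = p_threshold),
            class = "eben_control")
}

#' Marginal log-posterior in a coefficient precision
#'
#' Evaluates `L(alpha) = 1/2 [log(alpha/(alpha+1+s)) + q^2/(alpha+1+s)] -
#' lambda2/alpha`. `L(Inf) = 0` (the pruned state is the reference level).
#'
#' @param alpha precision value(s), strictly positive (may be `Inf`).
#' @param s,q sparsity and quality statistics of the candidate feature.
#' @param lambda2 second elastic-net hyperparameter.
#' @return `L(alpha)`, vectorized over the inputs.
#' @export
log_posterior_alpha <- function(alpha, s, q, lambda2 = 0) {
  if (any(alpha <= 0 | is.na(alpha))) stop("alpha must be strictly positive")
  d <- alpha + 1 + s
  out <- 0.5 * (log(alpha / d) + q^2 / d) - lambda2 / alpha
  out[is.infinite(alpha)] <- 0
  out
}

#' Optimal coefficient precision for given (s, q)
#'
#' Returns the maximizer of the marginal log-posterior, or `Inf` when the
#' feature should be pruned. A finite value is possible only when the
#' inclusion gate `q^2 - s > lambda1 + 2*lambda2` holds strictly; the finite
#' maximizer additionally requires `q^2 > 1 + s + 2*lambda2`, otherwise the
#' posterior is monotone increasing in alpha and the supremum sits at
#' infinity. The stationarity condition of `L` is an exact quadratic in
#' alpha, so the maximizer is computed in closed form:
#' `(1+s-q^2+2*lambda2) a^2 + ((1+s)^2+4*lambda2*(1+s)) a + 2*lambda2*(1+s)^2 = 0`.
#' With `lambda2 = 0` this reduces to `(1+s)^2 / (q^2 - 1 - s)`.
#'
#' @param s,q sparsity and quality statistics (vectorized).
#' @param lambda1,lambda2 elastic-net hyperparameters, non-negative scalars.
#' @return Precision value(s) in `(0, Inf]`.
#' @export
optimal_alpha <- function(s, q, lambda1 = 0, lambda2 = 0) {
  stopifnot(length(lambda1) == 1L, length(lambda2) == 1L,
            is.finite(lambda1), is.finite(lambda2),
            lambda1 >= 0, lambda2 >= 0)
  s <- as.numeric(s); q <- as.numeric(q)
  if (any(s < 0 & is.finite(s), na.rm = TRUE)) stop("s must be non-negative")
  out <- rep(Inf, length(s))
  gate <- is.finite(s) & is.finite(q) & (q^2 - s > lambda1 + 2 * lambda2)
  cc <- 1 + s
  A <- cc - q^2 + 2 * lambda2
  ok <- gate & (A < 0)
  if (any(ok)) {
    a <- A[ok]; c1 <- cc[ok]
    b <- c1^2 + 4 * lambda2 * c1
    cq <- 2 * lambda2 * c1^2
    disc <- b^2 - 4 * a * cq
    out[ok] <- (b + sqrt(pmax(disc, 0))) / (-2 * a)
  }
  out
}

# ---- active-set state machinery (internal) ----------------------------------

# Recompute the posterior and the s/q caches exactly from the current active
# set, in the whitened parameterization:
#   W    = (diag(alpha) + Xa' Xa)^-1        (posterior covariance / sigma0^2)
#   beta = W Xa' ytilde                     (posterior mean)
#   S_k  = x_k'x_k - b_k' W b_k,   b_k = Xa' x_k   (cached rows of B)
#   Q_k  = (x_k'ytilde - b_k' W u) / sigma0, u = Xa' ytilde
# For active features s,q are deflated so the feature's own contribution to
# the marginal covariance is removed: s = alpha S/(alpha-S), q = alpha Q/(alpha-S).
eben_refresh <- function(st) {
  sig <- sqrt(st$sigma0_sq)
  a <- length(st$active)
  if (a == 0L) {
    st$S <- st$design$xx
    st$Q <- st$xy / sig
    st$W <- matrix(0, 0, 0)
    st$beta <- numeric(0)
  } else {
    G <- st$B[, st$active, drop = FALSE]
    G <- (G + t(G)) / 2
    M <- G + diag(st$alpha, a)
    R <- tryCatch(chol(M), error = function(e) {
      stop("posterior covariance lost positive-definiteness (active set: ",
           paste(st$active, collapse = ","), ")", call. = FALSE)
    })
    W <- chol2inv(R)
    u <- st$xy[st$active]
    WB <- W %*% st$B
    st$S <- st$design$xx - colSums(st$B * WB)
    st$Q <- (st$xy - drop(crossprod(st$B, W %*% u))) / sig
    st$W <- W
    st$beta <- drop(W %*% u)
  }
  st$s <- st$S
  st$q <- st$Q
  if (a > 0L) {
    den <- st$alpha - st$S[st$active]
    sa <- st$alpha * st$S[st$active] / den
    qa <- st$alpha * st$Q[st$active] / den
    bad <- den <= .Machine$double.eps | !is.finite(sa)
    sa[bad] <- Inf
    qa[bad] <- 0
    st$s[st$active] <- sa
    st$q[st$active] <- qa
  }
  if (anyNA(st$s) || anyNA(st$q)) {
    stop("non-finite s/q statistics for feature(s) ",
         paste(which(is.na(st$s) | is.na(st$q)), collapse = ","))
  }
  st
}

# Initialize solver state: mu = mean(y), ytilde = y - mu,
# sigma0^2 = 0.1 * ytilde'ytilde / n; the initial candidate feature is
# argmax_i |x_i' ytilde| (lowest index on ties).
eben_init_state <- function(design, y, lambda1 = 0, lambda2 = 0) {
  n <- design$n
  y <- as.numeric(y)
  stopifnot(length(y) == n)
  if (n < 3L) stop("need at least 3 samples")
  if (design_ncand(design) < 1L) stop("need at least one candidate feature")
  if (!all(is.finite(y))) stop("phenotype contains non-finite values")
  mu <- mean(y)
  yt <- y - mu
  if (sum(yt^2) <= .Machine$double.eps * n) stop("phenotype is constant")
  sigma0_sq <- 0.1 * sum(yt^2) / n
  xy <- design_cross_vec(design, yt)
  st <- list(design = design, n = n, mu = mu, yt = yt,
             sigma0_sq = sigma0_sq, xy = xy,
             lambda1 = lambda1, lambda2 = lambda2,
             active = integer(0), alpha = numeric(0),
             Xa = matrix(0, n, 0L),
             B = matrix(0, 0L, design_ncand(design)),
             init_feature = unname(which.max(abs(xy))))
  eben_refresh(st)
}

# Exposed wrapper for the cached statistics of one feature.
compute_sq <- function(st, feature) {
  c(s = st$s[feature], q = st$q[feature])
}

# Greedy action selection: for every candidate compute alpha* and the ascent
# gain dL = L(alpha*) - L(alpha_current), with L(Inf) = 0 for inactive
# features. The implied action is add (inactive, finite alpha*), re-estimate
# (active, finite alpha*) or delete (active, alpha* = Inf). Returns the action
# with the largest strictly positive gain (lowest feature index on ties), or a
# no-op token. `restrict` limits the candidate set (used to honour the
# highest-correlation initialization).
select_update <- function(st, restrict = NULL) {
  astar <- optimal_alpha(st$s, st$q, st$lambda1, st$lambda2)
  Lstar <- log_posterior_alpha(astar, st$s, st$q, st$lambda2)
  Lcur <- numeric(length(st$s))
  if (length(st$active)) {
    Lcur[st$active] <- log_posterior_alpha(st$alpha, st$s[st$active],
                                           st$q[st$active], st$lambda2)
  }
  dL <- Lstar - Lcur
  is_active <- logical(length(st$s))
  is_active[st$active] <- TRUE
  # inactive feature with infinite alpha*: nothing to do
  dL[!is_active & !is.finite(astar)] <- -Inf
  # deletion gain: L(Inf) - L(alpha_cur) = -L(alpha_cur); Lstar is already 0
  any_finite <- any(is.finite(astar))
  if (!is.null(restrict)) {
    keep <- rep(-Inf, length(dL))
    keep[restrict] <- dL[restrict]
    dL <- keep
  }
  j <- unname(which.max(dL))
  if (!length(j) || dL[j] <= 0) {
    return(list(type = "none", any_finite = any_finite))
  }
  type <- if (!is_active[j]) "add" else if (is.finite(astar[j])) "reestimate" else "delete"
  list(type = type, feature = j, alpha = unname(astar[j]), delta_L = unname(dL[j]),
       any_finite = any_finite)
}

# Apply a selected action and refresh all caches.
apply_update <- function(st, action) {
  if (action$type == "none") return(st)
  j <- action$feature
  if (action$type == "add") {
    xcol <- design_cols(st$design, j)
    st$Xa <- cbind(st$Xa, xcol)
    st$B <- rbind(st$B, design_cross_vec(st$design, drop(xcol)))
    st$active <- c(st$active, j)
    st$alpha <- c(st$alpha, action$alpha)
  } else {
    pos <- match(j, st$active)
    if (is.na(pos)) stop("action refers to a feature outside the active set")
    if (action$type == "reestimate") {
      st$alpha[pos] <- action$alpha
    } else {
      st$active <- st$active[-pos]
      st$alpha <- st$alpha[-pos]
      st$Xa <- st$Xa[, -pos, drop = FALSE]
      st$B <- st$B[-pos, , drop = FALSE]
    }
  }
  eben_refresh(st)
}

# Evidence-style noise variance update:
#   sigma0^2 <- ||ytilde - Xa beta||^2 / (n - sum(gamma)),
#   gamma_k = 1 - alpha_k * W_kk   (W = posterior covariance / sigma0^2).
# Applied once per outer pass; a non-positive denominator keeps the previous
# value with a warning, and the estimate is floored at 1e-12.
update_noise_variance <- function(st) {
  if (length(st$active) == 0L) return(st)
  gam <- 1 - st$alpha * diag(st$W)
  den <- st$n - sum(gam)
  if (den <= 0) {
    warning("noise-variance update skipped: effective degrees of freedom <= 0")
    return(st)
  }
  resid <- st$yt - drop(st$Xa %*% st$beta)
  st$sigma0_sq <- max(sum(resid^2) / den, 1e-12)
  eben_refresh(st)
}

# Convergence over alpha maps (named vectors keyed by feature index):
# converged iff (i) no finite alpha was proposed this round, OR the active
# membership is unchanged and (ii) max |d alpha| < alpha_change_tol AND
# (iii) ||d alpha||_2 < norm_change_tol over features finite in both states.
check_convergence <- function(prev_alpha, new_alpha, had_candidate, control) {
  if (!had_candidate) return(TRUE)
  if (!setequal(names(prev_alpha), names(new_alpha))) return(FALSE)
  common <- intersect(names(prev_alpha), names(new_alpha))
  if (!length(common)) return(TRUE)
  d <- abs(new_alpha[common] - prev_alpha[common])
  max(d) < control$alpha_change_tol && sqrt(sum(d^2)) < control$norm_change_tol
}

alpha_map <- function(st) {
  stats::setNames(st$alpha, as.character(st$active))
}

# Posterior t-tests on the selected coefficients: se from the posterior
# covariance diagonal, t = beta/se, two-sided p from Student-t with
# df = n - |active| - 1 (the intercept is absorbed in mu).
posterior_t_tests <- function(st, control) {
  a <- length(st$active)
  df <- st$n - a - 1L
  if (a > 0L && df <= 0L) {
    stop("model over-saturated: residual degrees of freedom <= 0")
  }
  if (a == 0L) {
    coef <- data.frame(feature = character(0), index = integer(0),
                       beta = numeric(0), se = numeric(0),
                       t = numeric(0), p = numeric(0),
                       significant = logical(0), stringsAsFactors = FALSE)
  } else {
    se <- sqrt(st$sigma0_sq) * sqrt(diag(st$W))
    tval <- st$beta / se
    p <- 2 * pt(-abs(tval), df)
    coef <- data.frame(feature = st$design$keys[st$active],
                       index = st$active, beta = st$beta, se = se,
                       t = tval, p = p,
                       significant = p < control$p_threshold,
                       stringsAsFactors = FALSE)
    rownames(coef) <- NULL
  }
  structure(list(mu = st$mu, coefficients = coef, sigma0_sq = st$sigma0_sq,
                 lambda1 = st$lambda1, lambda2 = st$lambda2,
                 n = st$n, df = df,
                 active = st$active, alpha = alpha_map(st),
                 design_kind = st$design$kind),
            class = "eben_fit")
}

#' Fit the empirical Bayesian elastic net
#'
#' Greedy coordinate-ascent selection over candidate features: initialize at
#' the feature most correlated with the centered phenotype, then repeatedly
#' apply the single add / re-estimate / delete action with the largest gain in
#' the marginal log-posterior, re-estimating the noise variance after each
#' action, until the convergence criteria are met (no finite precision
#' proposed, or per-feature and Euclidean changes in alpha below tolerance).
#' Selected coefficients are then tested with posterior t-tests. The fit is
#' deterministic given its inputs.
#'
#' @param X numeric matrix (samples x features) or an `eben_design` from
#'   [main_effect_design()] / [interaction_design()].
#' @param y numeric phenotype vector.
#' @param lambda1,lambda2 non-negative elastic-net hyperparameters; `lambda1`
#'   acts only in the inclusion gate `q^2 - s > lambda1 + 2*lambda2`,
#'   `lambda2` also penalizes the marginal log-posterior.
#' @param control solver settings from [eben_control()].
#' @return An object of class `eben_fit`: `mu`, `coefficients` (feature, beta,
#'   se, t, p, significant), `sigma0_sq`, the active set with its `alpha`
#'   values, and `diagnostics` (iterations, convergence flag, the gain of
#'   every applied action).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 2 * X[, 2] + rnorm(100, sd = 0.5)
#' fit <- eben_fit(X, y)
#' fit$coefficients
#' @export
eben_fit <- function(X, y, lambda1 = 0, lambda2 = 0, control = eben_control()) {
  design <- if (inherits(X, "eben_design")) X else main_effect_design(X)
  st <- eben_init_state(design, y, lambda1, lambda2)
  delta_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  restrict <- st$init_feature
  while (iter < control$max_iterations) {
    iter <- iter + 1L
    act <- select_update(st, restrict = restrict)
    if (act$type == "none" && !is.null(restrict)) {
      # initial candidate not admissible: fall back to the full candidate set
      act <- select_update(st)
    }
    restrict <- NULL
    if (act$type == "none") {
      converged <- TRUE
      break
    }
    prev <- alpha_map(st)
    st <- apply_update(st, act)
    st <- update_noise_variance(st)
    delta_trace <- c(delta_trace, act$delta_L)
    if (check_convergence(prev, alpha_map(st), act$any_finite, control)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EBEN did not converge within ", control$max_iterations,
            " iterations")
  }
  fit <- posterior_t_tests(st, control)
  fit$diagnostics <- list(iterations = iter, converged = converged,
                          delta_L = delta_trace)
  fit$control <- control
  fit
}

#' @export
print.eben_fit <- function(x, ...) {
  cat("Empirical Bayesian elastic net fit\n")
  cat(sprintf("  n = %d, lambda1 = %.4g, lambda2 = %.4g, sigma0^2 = %.4g\n",
              x$n, x$lambda1, x$lambda2, x$sigma0_sq))
  cat(sprintf("  %d selected feature(s), %d significant at p < %g\n",
              nrow(x$coefficients), sum(x$coefficients$significant),
              x$control$p_threshold))
  if (nrow(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}

# Held-out prediction used by cross-validation: mu + columns %*% beta over the
# selected features, with columns rebuilt from the training design's metadata.
predict_eben <- function(fit, design, Xnew) {
  if (!length(fit$active)) return(rep(fit$mu, nrow(Xnew)))
  cols <- design_newdata_cols(design, fit$active, Xnew)
  drop(fit$mu + cols %*% fit$coefficients$beta)
}
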