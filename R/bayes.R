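#' Prior settings for the binomial mixed models
#'
#' Proper priors for the allelic-imbalance models. All scales are on the
#' logit scale.
#' * `beta0_sd` — SD of the Normal prior on the intercept `beta0` (the degree
#'   of allelic imbalance); the default 3 is weakly informative (an imbalance
#'   of |logit| = 3 is an alt fraction of 0.95).
#' * `sigma_gamma_scale` — scale of the Half-Normal prior on the SD of the
#'   per-twin random effect `gamma_i`.
#' * `sigma_status_scale` — scale of the Half-Normal prior on the SD of the
#'   mean-zero two-level disease-status random effect used by the
#'   quantification model.
#' * `delta_sd` — SD of the unit-information Normal prior on the
#'   effect-coded disease-status effect (`+delta/2` affected, `-delta/2`
#'   unaffected) in the Bayes-factor model M1. Bayes factors are
#'   prior-sensitive, so this value is stamped into outputs.
#'
#' @param beta0_sd,sigma_gamma_scale,sigma_status_scale,delta_sd Positive
#'   scalars.
#' @return A named list of class `ashm_priors`.
#' @export
ashm_priors <- function(beta0_sd = 3, sigma_gamma_scale = 1,
                        sigma_status_scale = 1, delta_sd = 1) {
  stopifnot(beta0_sd > 0, sigma_gamma_scale > 0, sigma_status_scale > 0,
            delta_sd > 0)
  structure(list(beta0_sd = beta0_sd, sigma_gamma_scale = sigma_gamma_scale,
                 sigma_status_scale = sigma_status_scale, delta_sd = delta_sd),
            class = "ashm_priors")
}

#' Inference settings for the posterior / marginal-likelihood backend
#'
#' The backend integrates the per-twin random effects out of the likelihood
#' by adaptive Gauss-Hermite quadrature, finds the mode of the remaining
#' low-dimensional marginal posterior, forms a Laplace (Gaussian)
#' approximation there, and refines both the marginal likelihood and the
#' posterior summaries by importance sampling with a multivariate-t proposal
#' centred at the mode.
#'
#' @param n_draws Number of importance-sampling draws (0 = pure Laplace).
#' @param n_samples Number of equally weighted posterior draws of `beta0`
#'   returned by sampling-importance-resampling.
#' @param gh_nodes Number of Gauss-Hermite nodes for the random-effect
#'   integrals.
#' @param proposal_df Degrees of freedom of the t proposal (heavy tails guard
#'   against underdispersion of the Laplace covariance).
#' @param scale_inflate Multiplier on the Laplace covariance Cholesky factor.
#' @param seed Optional integer seed applied before drawing.
#' @return A named list of class `ashm_inference`.
#' @export
ashm_inference <- function(n_draws = 2000, n_samples = 2000, gh_nodes = 11,
                           proposal_df = 4, scale_inflate = 1.3,
                           seed = NULL) {
  stopifnot(n_draws >= 0, gh_nodes >= 5, proposal_df > 2, scale_inflate > 0)
  structure(list(n_draws = as.integer(n_draws),
                 n_samples = as.integer(n_samples),
                 gh_nodes = as.integer(gh_nodes),
                 proposal_df = proposal_df, scale_inflate = scale_inflate,
                 seed = seed),
            class = "ashm_inference")
}

# Gauss-Hermite nodes/weights (physicists': int e^{-x^2} f(x) dx = sum w f(x))
# via Golub-Welsch on the Jacobi matrix; cached per Q.
gh_cache <- new.env(parent = emptyenv())
gauss_hermite <- function(q) {
  key <- as.character(q)
  if (!is.null(gh_cache[[key]])) return(gh_cache[[key]])
  off <- sqrt(seq_len(q - 1) / 2)
  J <- matrix(0, q, q)
  J[cbind(seq_len(q - 1), seq_len(q - 1) + 1)] <- off
  J[cbind(seq_len(q - 1) + 1, seq_len(q - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  o <- order(nodes)
  res <- list(x = nodes[o], w = weights[o])
  gh_cache[[key]] <- res
  res
}

# ---- model specification ---------------------------------------------------
#
# The per-twin random effects gamma_i ~ N(0, sigma_gamma^2) are integrated
# out of the likelihood by adaptive Gauss-Hermite quadrature (the integrand
# is strictly log-concave in gamma, so the 1-D Newton mode search is safe).
# Remaining (outer) parameter layout (theta):
#   quant : beta0, z_s, log sigma_gamma, log sigma_status
#           with status deviation d = sigma_status * z_s (non-centred)
#   m1    : beta0, delta, log sigma_gamma
#   m0    : beta0, log sigma_gamma
# Status coding c_i = +1/2 affected, -1/2 unaffected ("quant"/"m1" only).
site_model_spec <- function(alt, n, affected, model = c("quant", "m1", "m0"),
                            priors = ashm_priors(), gh_nodes = 15) {
  model <- match.arg(model)
  k <- length(alt)
  stopifnot(length(n) == k, length(affected) == k, all(n >= 1))
  has_status <- model != "m0"
  hier_status <- model == "quant"
  cc <- if (has_status) ifelse(affected, 0.5, -0.5) else numeric(k)
  i_b0 <- 1L
  i_sv <- if (has_status) 2L else NA_integer_
  i_ug <- (if (has_status) 2L else 1L) + 1L
  i_us <- if (hier_status) i_ug + 1L else NA_integer_
  dim <- i_ug + as.integer(hier_status)
  p_b0 <- priors$beta0_sd
  p_gs <- priors$sigma_gamma_scale
  p_ss <- priors$sigma_status_scale
  p_d <- priors$delta_sd
  gh <- gauss_hermite(gh_nodes)

  # binomial normalizing constant, added once in lp_mat (independent of g)
  ll_const <- sum(lchoose(n, alt))

  # log integral over gamma for each element of the N x k matrices
  # eta0 (fixed part of the linear predictor) and sg (random-effect SD rows).
  # The binomial log likelihood is written as alt*eta - n*softplus(eta)
  # (without the lchoose constant), which is exact and much cheaper than
  # dbinom on large draw matrices.
  inner_ll <- function(eta0, sg_row) {
    N <- nrow(eta0)
    A <- matrix(alt, N, k, byrow = TRUE)
    M <- matrix(n, N, k, byrow = TRUE)
    SG <- matrix(sg_row, N, k)
    isg2 <- 1 / SG^2
    h_of <- function(g) {
      eta <- eta0 + g
      sp <- pmax(eta, 0) + log1p(exp(-abs(eta))) # softplus, overflow-safe
      A * eta - M * sp - 0.5 * g * g * isg2 - log(SG) - 0.918938533204673
    }
    # Newton for the mode of the strictly concave integrand
    g <- matrix(0, N, k)
    for (it in 1:8) {
      p <- plogis(eta0 + g)
      h1 <- (A - M * p) - g * isg2
      h2 <- -M * p * (1 - p) - isg2
      g <- g - pmin(4, pmax(-4, h1 / h2))
    }
    p <- plogis(eta0 + g)
    s <- 1 / sqrt(M * p * (1 - p) + isg2)
    # adaptive GH: int e^h dg ~ sqrt(2) s sum_j w_j exp(h(m+sqrt2 s x_j)+x_j^2)
    vals <- lapply(seq_along(gh$x), function(j) {
      h_of(g + sqrt(2) * s * gh$x[j]) + gh$x[j]^2 + log(gh$w[j])
    })
    mx <- Reduce(pmax, vals)
    mx0 <- ifelse(is.finite(mx), mx, 0)
    tot <- Reduce(`+`, lapply(vals, function(v) exp(v - mx0)))
    mx0 + log(tot) + 0.5 * log(2) + log(s)
  }

  # vectorized marginal log posterior over rows of a draw matrix
  lp_mat <- function(Theta) {
    if (is.null(dim(Theta))) Theta <- matrix(Theta, nrow = 1)
    N <- nrow(Theta)
    sg <- exp(Theta[, i_ug])
    d <- if (!has_status) numeric(N)
         else if (hier_status) exp(Theta[, i_us]) * Theta[, i_sv]
         else Theta[, i_sv]
    eta0 <- Theta[, i_b0] + tcrossprod(d, cc)
    out <- ll_const + rowSums(inner_ll(eta0, sg)) +
      dnorm(Theta[, i_b0], 0, p_b0, log = TRUE) +
      log(2) + dnorm(sg, 0, p_gs, log = TRUE) + Theta[, i_ug]
    if (has_status) {
      if (hier_status) {
        ss <- exp(Theta[, i_us])
        out <- out + dnorm(Theta[, i_sv], log = TRUE) +
          log(2) + dnorm(ss, 0, p_ss, log = TRUE) + Theta[, i_us]
      } else {
        out <- out + dnorm(Theta[, i_sv], 0, p_d, log = TRUE)
      }
    }
    out
  }
  lp <- function(theta) lp_mat(matrix(theta, nrow = 1))[1]

  init <- function() {
    theta0 <- numeric(dim)
    frac <- (sum(alt) + 0.5) / (sum(n) + 1)
    theta0[i_b0] <- qlogis(pmin(0.98, pmax(0.02, frac)))
    theta0[i_ug] <- log(0.5)
    if (hier_status) theta0[i_us] <- log(0.5)
    theta0
  }

  list(lp = lp, lp_mat = lp_mat, init = init, dim = dim,
       idx = list(beta0 = i_b0, status = i_sv, log_sigma_gamma = i_ug,
                  log_sigma_status = i_us),
       model = model, k = k, cc = cc)
}

# ---- MAP / Laplace / importance sampling -----------------------------------

fit_map <- function(spec) {
  neg_lp <- function(th) -spec$lp(th)
  fit <- optim(spec$init(), neg_lp, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  fit <- optim(fit$par, neg_lp, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-12))
  list(par = fit$par, lp = -fit$value)
}

# negative Hessian of the log posterior by central second differences
hessian_fd <- function(lp, theta, h = 1e-3) {
  d <- length(theta)
  H <- matrix(0, d, d)
  f0 <- lp(theta)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (lp(theta + ei) - 2 * f0 + lp(theta - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (lp(theta + ei + ej) - lp(theta + ei - ej) -
           lp(theta - ei + ej) + lp(theta - ei - ej)) / (4 * h^2)
    }
  }
  -H
}

safe_chol <- function(H) {
  jitter <- 0
  for (i in 0:6) {
    R <- tryCatch(chol(H + diag(jitter, nrow(H))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jitter <- if (jitter == 0) 1e-8 else jitter * 100
  }
  stop("Hessian not positive definite at the posterior mode")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Marginal likelihood and posterior draws for one site model.
# Laplace at the mode of the (random-effects-marginalized) posterior,
# refined by importance sampling with a multivariate-t proposal; the t tails
# dominate the Gaussian tail of the Laplace approximation, so the estimator
# has finite variance for these log-concave-like targets.
marginal_likelihood <- function(spec, settings = ashm_inference()) {
  if (!is.null(settings$seed)) set.seed(settings$seed)
  map <- fit_map(spec)
  H <- hessian_fd(spec$lp, map$par)
  R <- safe_chol(H) # H = R'R
  d <- spec$dim
  logdet_H <- 2 * sum(log(diag(R)))
  logml_laplace <- map$lp + 0.5 * d * log(2 * pi) - 0.5 * logdet_H
  if (settings$n_draws == 0) {
    return(list(log_ml = logml_laplace, logml_laplace = logml_laplace,
                map = map$par, lp_map = map$lp, draws = NULL, weights = NULL,
                ess = NA_real_))
  }
  N <- settings$n_draws
  df <- settings$proposal_df
  one_round <- function(center, L, logdet_Sigma) {
    Z <- matrix(rnorm(N * d), N, d)
    W <- rchisq(N, df) / df
    X <- sweep(Z %*% t(L), 1, sqrt(W), "/")
    X <- sweep(X, 2, center, "+")
    quad <- rowSums(Z^2) / W
    logq <- lgamma((df + d) / 2) - lgamma(df / 2) -
      0.5 * d * log(df * pi) - 0.5 * logdet_Sigma -
      0.5 * (df + d) * log1p(quad / df)
    lw <- spec$lp_mat(X) - logq
    lse <- log_sum_exp(lw)
    w <- exp(lw - lse)
    list(log_ml = lse - log(N), draws = X, weights = w, ess = 1 / sum(w^2))
  }
  L <- settings$scale_inflate * backsolve(R, diag(d)) # Sigma = L %*% t(L)
  res <- one_round(map$par, L, 2 * d * log(settings$scale_inflate) -
                     logdet_H)
  if (res$ess < N / 4) {
    # adapt: moment-match the t proposal to the weighted first-round draws
    # (curved ridges, e.g. in the hierarchical status scale, leave the
    # Laplace covariance underdispersed)
    mu <- colSums(res$draws * res$weights)
    Xc <- sweep(res$draws, 2, mu, "-")
    Sg <- crossprod(Xc * sqrt(res$weights)) * settings$scale_inflate^2
    Rw <- safe_chol(Sg)
    res <- one_round(mu, t(Rw), 2 * sum(log(diag(Rw))))
  }
  list(log_ml = res$log_ml, logml_laplace = logml_laplace, map = map$par,
       lp_map = map$lp, draws = res$draws, weights = res$weights,
       ess = res$ess)
}

# weighted type-1 quantile
wquantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
}
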