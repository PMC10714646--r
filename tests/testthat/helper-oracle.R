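# Independent brute-force oracles. These deliberately avoid the package's
# computational shortcuts: exact-test p-values by explicit pmf summation,
# BH by the naive O(m^2) definition, and model marginal likelihoods by dense
# trapezoid-grid numerical integration (no Gauss-Hermite, no Laplace, no
# importance sampling).

# two-sided exact binomial p against 0.5 by pmf enumeration
oracle_binom_p <- function(alt, ref) {
  n <- alt + ref
  pmf <- dbinom(0:n, n, 0.5)
  sum(pmf[pmf <= pmf[alt + 1] * (1 + 1e-9)])
}

# naive BH step-up: q_i = min over j >= rank(i) of m * p_(j) / j
oracle_bh <- function(p, q = 0.10) {
  m <- length(p)
  o <- order(p)
  qs <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    ri <- which(o == i) # rank of p[i]
    for (j in seq(ri, m)) {
      cand <- min(cand, m * p[o[j]] / j)
    }
    qs[i] <- min(1, cand)
  }
  list(q_value = qs, rejected = qs < q)
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # foreground size
  n_ <- c + d         # background size
  k <- a + c          # annotation column margin
  x <- max(0, k - n_):min(m, k)
  pmf <- dhyper(x, m, n_, k)
  obs <- dhyper(a, m, n_, k)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# trapezoid weights for a (possibly non-uniform) grid
trap_w <- function(x) {
  n <- length(x)
  c(x[2] - x[1], x[3:n] - x[1:(n - 2)], x[n] - x[n - 1]) / 2
}

log_row_sum_exp <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx0 <- ifelse(is.finite(mx), mx, 0)
  mx0 + log(rowSums(exp(M - mx0)))
}

# log of the per-individual likelihood integrated over the random effect,
# by trapezoid quadrature: rows = eta0 values, cols = sigma_gamma values
oracle_inner <- function(alt, n, eta0_grid, sg_grid) {
  out <- matrix(NA_real_, length(eta0_grid), length(sg_grid))
  for (j in seq_along(sg_grid)) {
    sg <- sg_grid[j]
    if (sg < 0.12) {
      # scaled grid: g = sg * z keeps resolution for small sigmas
      z <- seq(-6, 6, by = 0.04)
      lwt <- dnorm(z, log = TRUE) + log(trap_w(z))
      g <- sg * z
    } else {
      g <- seq(-6.5, 6.5, by = 0.025)
      lwt <- dnorm(g, 0, sg, log = TRUE) + log(trap_w(g))
    }
    ll <- dbinom(alt, n, plogis(outer(eta0_grid, g, "+")), log = TRUE)
    out[, j] <- log_row_sum_exp(sweep(ll, 2, lwt, "+"))
  }
  out
}

# Dense-grid log marginal likelihoods and beta0 posterior means for all
# three site models at once (they share the per-individual inner integrals):
#   m1    — status effect with fixed Normal(0, delta_sd) prior
#   m0    — no status effect
#   quant — hierarchical mean-zero two-level status effect; the Half-Normal
#           scale is integrated out of the prior. That marginal prior has a
#           log singularity at 0, so exact *cell probabilities* are used
#           (P(lo < d < hi) integrated over the scale by quadrature) rather
#           than point densities times cell widths.
oracle_site <- function(alt, n, affected, priors = ashm_priors(),
                        step = 0.1) {
  k <- length(alt)
  cc <- ifelse(affected, 0.5, -0.5)
  b0g <- seq(-7.2, 7.2, by = step)
  dg <- b0g
  lw_b0 <- dnorm(b0g, 0, priors$beta0_sd, log = TRUE) + log(trap_w(b0g))
  lw_d_fixed <- dnorm(dg, 0, priors$delta_sd, log = TRUE) + log(trap_w(dg))
  s_scale <- priors$sigma_status_scale
  ssg <- exp(seq(log(1e-5), log(8), length.out = 2000))
  wss <- trap_w(ssg)
  hn <- sqrt(2 / pi) / s_scale * exp(-ssg^2 / (2 * s_scale^2))
  mids <- c(-Inf, (dg[-1] + dg[-length(dg)]) / 2, Inf)
  lw_d_hier <- log(vapply(seq_along(dg), function(i) {
    sum(hn * (pnorm(mids[i + 1] / ssg) - pnorm(mids[i] / ssg)) * wss)
  }, numeric(1)))
  sgg <- c(0.0005, 0.00125, 0.0025, 0.005, 0.01,
           seq(0.02, 0.1, by = 0.02), seq(0.125, 0.5, by = 0.025),
           seq(0.55, 1.6, by = 0.05), seq(1.7, 3.6, by = 0.1))
  lw_sg <- log(2) + dnorm(sgg, 0, priors$sigma_gamma_scale, log = TRUE) +
    log(trap_w(sgg))
  nb <- length(b0g); nd <- length(dg); ns <- length(sgg)

  # eta0 = beta0 + c_i * d/2 lies on a half-step lattice
  h <- step / 2
  eta_lo <- min(b0g) + min(dg) / 2
  eta_all <- seq(eta_lo, max(b0g) + max(dg) / 2 + 1e-9, by = h)
  eta_idx <- function(sign_i) {
    e <- outer(b0g, sign_i * dg / 2, "+")
    matrix(as.integer(round((e - eta_lo) / h)) + 1L, nb, nd)
  }
  idx_plus <- eta_idx(1); idx_minus <- eta_idx(-1)
  idx_b0 <- as.integer(round((b0g - eta_lo) / h)) + 1L

  A <- array(0, dim = c(nb, nd, ns)) # joint loglik, status models
  A0 <- matrix(0, nb, ns)            # joint loglik, m0
  for (i in seq_len(k)) {
    inner_i <- oracle_inner(alt[i], n[i], eta_all, sgg) # |eta| x |sg|
    idx <- if (cc[i] > 0) idx_plus else idx_minus
    for (j in seq_len(ns)) {
      A[, , j] <- A[, , j] + matrix(inner_i[idx, j], nb, nd)
    }
    A0 <- A0 + inner_i[idx_b0, ]
  }

  summarize3 <- function(lw_d) {
    B <- A + rep(lw_b0, times = nd * ns) +
      rep(rep(lw_d, each = nb), times = ns) +
      rep(lw_sg, each = nb * nd)
    log_ml <- log_row_sum_exp(matrix(as.vector(B), nrow = 1))
    pw <- exp(B - as.numeric(log_ml))
    list(log_ml = as.numeric(log_ml),
         beta0_mean = sum(apply(pw, 1, sum) * b0g))
  }
  B0 <- sweep(sweep(A0, 1, lw_b0, "+"), 2, lw_sg, "+")
  ml0 <- log_row_sum_exp(matrix(as.vector(B0), nrow = 1))
  m0 <- list(log_ml = as.numeric(ml0),
             beta0_mean = sum(rowSums(exp(B0 - as.numeric(ml0))) * b0g))
  list(m1 = summarize3(lw_d_fixed), quant = summarize3(lw_d_hier), m0 = m0)
}

# oracle log Bayes factor M1 vs M0
oracle_log_bf <- function(alt, n, affected, priors = ashm_priors()) {
  o <- oracle_site(alt, n, affected, priors)
  o$m1$log_ml - o$m0$log_ml
}
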