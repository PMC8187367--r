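# Internal: BUGS model construction for one local distribution, plus the
# Beta-angle representation of the LKJ-Cholesky prior on the personal-effect
# correlation matrix.

# Pair bookkeeping for the strictly-lower-triangular angles of a q x q
# Cholesky factor. Row j, column m < j maps to pair index idx[j, m]; the Beta
# shape for column m under LKJ(eta) is a_m = (q - m + 2*eta - 1) / 2, which
# makes C = LL' exactly LKJ(eta)-distributed.
.lkj_pairs <- function(q, eta) {
  n_pair <- q * (q - 1L) / 2L
  idx <- matrix(0L, q, q)
  a <- numeric(max(n_pair, 1L))
  t <- 0L
  if (q >= 2) {
    for (j in 2:q) for (m in seq_len(j - 1L)) {
      t <- t + 1L
      idx[j, m] <- t
      a[t] <- (q - m + 2 * eta - 1) / 2
    }
  }
  list(n_pair = n_pair, idx = idx, a = a)
}

# Rebuild the lower-triangular Cholesky factor of the correlation matrix from
# one draw of the angle-cosine latents u (on the Beta scale, x = 2u - 1).
.chol_from_u <- function(u, q) {
  L <- diag(q)
  if (q >= 2) {
    t <- 0L
    for (j in 2:q) {
      sp <- 1
      for (m in seq_len(j - 1L)) {
        t <- t + 1L
        x <- 2 * u[t] - 1
        L[j, m] <- x * sp
        sp <- sp * sqrt(max(1 - x^2, 0))
      }
      L[j, j] <- sp
    }
  }
  L
}

# Draw a Cholesky factor of an LKJ(eta)-distributed correlation matrix.
.rlkj_chol <- function(q, eta) {
  pr <- .lkj_pairs(q, eta)
  if (pr$n_pair == 0) return(diag(q))
  u <- stats::rbeta(pr$n_pair, pr$a, pr$a)
  .chol_from_u(u, q)
}

# BUGS code for one response. Data nodes expected: y, y_prev, X (N x P),
# Z (N x Q), subj, prev, arf, N, S, P, Q, scale_int, plus per-prior/LKJ nodes.
.mebn_model_code <- function(family, prior_kind, q, ar1) {
  stopifnot(family %in% c("normal", "gamma"),
            prior_kind %in% c("vague", "rhs"))
  slope_prior <- if (prior_kind == "vague") "
  for (j in 2:P) { beta[j] ~ dt(0, pow(scale_slope,-2), 1) }
" else "
  tau_g ~ dt(0, pow(tau0,-2), 1) T(0,)
  c2inv ~ dgamma(nu/2, nu*s2/2)
  c2 <- 1/c2inv
  for (j in 2:P) {
    lambda[j] ~ dt(0, 1, 1) T(0,)
    lt2[j] <- c2*pow(lambda[j],2) / (c2 + pow(tau_g,2)*pow(lambda[j],2))
    beta[j] ~ dnorm(0, 1/(pow(tau_g,2)*lt2[j]))
  }
"
  lkj <- if (q >= 2) "
  for (t in 1:n_pair) { u[t] ~ dbeta(a_lkj[t], a_lkj[t]) }
  Lc[1,1] <- 1
  for (j in 2:Q) {
    sp[j,1] <- 1
    for (m in 1:(j-1)) {
      xang[j,m] <- 2*u[idx[j,m]] - 1
      Lc[j,m] <- xang[j,m]*sp[j,m]
      sp[j,m+1] <- sp[j,m]*sqrt(1 - pow(xang[j,m],2))
    }
    Lc[j,j] <- sp[j,j]
  }
" else "
  Lc[1,1] <- 1
"
  ar <- if (ar1) "
  rho ~ dunif(-1, 1)
  for (r in 1:N) {
    mu_adj[r] <- mu[r] + rho * arf[r] * (y_prev[r] - mu[prev[r]])
  }
" else "
  for (r in 1:N) { mu_adj[r] <- mu[r] }
"
  lik <- if (family == "gamma") "
  alpha ~ dgamma(2, 0.1)
  for (r in 1:N) {
    y[r] ~ dgamma(alpha, alpha / max(mu_adj[r], 1.0E-6))
  }
" else "
  sigma_eps ~ dt(0, 1, 3) T(0,)
  for (r in 1:N) {
    y[r] ~ dnorm(mu_adj[r], pow(sigma_eps,-2))
  }
"
  paste0("model {
  beta[1] ~ dt(0, pow(scale_int,-2), 1)
", slope_prior, lkj, "
  for (j in 1:Q) { sigma_b[j] ~ dt(0, 1, 3) T(0,) }
  for (k in 1:S) {
    for (j in 1:Q) {
      z[k,j] ~ dnorm(0, 1)
      b[k,j] <- sigma_b[j] * inprod(Lc[j,1:j], z[k,1:j])
    }
  }
  for (r in 1:N) {
    mu[r] <- inprod(X[r,], beta) + inprod(Z[r,], b[subj[r],])
  }
", ar, lik, "}
")
}
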