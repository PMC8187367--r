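#' Compose a personal effect from its non-centered parts
#'
#' The personal deviation of subject \eqn{k} is generated as
#' \eqn{b_k = T L z_k} with \eqn{T = diag(\sigma_b)}, \eqn{L} the Cholesky
#' factor of the personal-effect correlation matrix, and \eqn{z_k} standard
#' normal. This helper performs that algebra for one draw.
#'
#' @param sigma_b vector of personal-effect standard deviations.
#' @param L lower-triangular Cholesky factor of the correlation matrix.
#' @param z standard-normal latent vector.
#' @return the personal deviation vector \eqn{b_k}.
#' @examples
#' compose_personal_effect(c(2, 1), rbind(c(1, 0), c(0.6, 0.8)), c(1, 1))
#' # -> c(2, 1.4)
#' @export
compose_personal_effect <- function(sigma_b, L, z) {
  L <- as.matrix(L)
  stopifnot(length(sigma_b) == nrow(L), nrow(L) == ncol(L),
            length(z) == ncol(L))
  as.numeric(diag(x = sigma_b, nrow = length(sigma_b)) %*% L %*% z)
}

#' General-plus-personal linear predictor
#'
#' Evaluates \eqn{\mu = X_{row} \beta + Z_{row} b_k}: the general part shared
#' by all subjects plus the personal deviation of subject \eqn{k}.
#'
#' @param x_row general design row (includes the intercept column).
#' @param z_row personal design row.
#' @param beta general coefficients.
#' @param b_k personal deviations for the subject.
#' @return the scalar expected value \eqn{\mu}.
#' @export
linear_predictor <- function(x_row, z_row, beta, b_k) {
  if (length(x_row) != length(beta))
    stop("dimension mismatch between x_row and beta")
  if (length(z_row) != length(b_k))
    stop("dimension mismatch between z_row and b_k")
  sum(x_row * beta) + sum(z_row * b_k)
}

#' Personal effects of one subject
#'
#' Summarizes, per personal predictor, the posterior of the subject's
#' deviation \eqn{b_k} and of the full personal effect \eqn{\beta + b_k}
#' (posterior mean and central 90% credible interval).
#'
#' @param fit a `mebn_local` or a `mebn` network.
#' @param subject subject identifier present in the fitted data.
#' @param response for a network fit, which response (default: all, row-bound).
#' @return a data frame with one row per (response, personal predictor).
#' @export
personal_effects <- function(fit, subject, response = NULL) {
  if (inherits(fit, "mebn")) {
    responses <- if (is.null(response)) fit$spec$responses else response
    out <- lapply(responses, function(r) personal_effects(fit$locals[[r]], subject))
    return(do.call(rbind, out))
  }
  stopifnot(inherits(fit, "mebn_local"))
  k <- match(as.character(subject), fit$subjects)
  if (is.na(k)) stop("unknown subject: ", subject)
  bq <- fit$draws$b[, k, , drop = FALSE]  # ndraw x 1 x Q
  Q <- length(fit$personal)
  out <- data.frame(response = fit$response, predictor = fit$personal,
                    stringsAsFactors = FALSE)
  bm <- matrix(bq, nrow = dim(bq)[1], ncol = Q)
  beta_p <- fit$draws$beta[, fit$personal, drop = FALSE]
  eff <- beta_p + bm
  out$b_mean <- colMeans(bm)
  out$b_q05 <- apply(bm, 2, quantile, 0.05)
  out$b_q95 <- apply(bm, 2, quantile, 0.95)
  out$effect_mean <- colMeans(eff)
  out$effect_q05 <- apply(eff, 2, quantile, 0.05)
  out$effect_q95 <- apply(eff, 2, quantile, 0.95)
  rownames(out) <- NULL
  out
}

#' Posterior summary of the personal-effect correlation matrix
#'
#' Reconstructs \eqn{C = L L'} for every posterior draw and returns the
#' elementwise posterior mean with central 90% intervals. The diagonal is
#' exactly one by construction.
#'
#' @param fit a `mebn_local`.
#' @return a list with matrices `mean`, `q05`, `q95` (personal x personal).
#' @export
effect_correlations <- function(fit) {
  stopifnot(inherits(fit, "mebn_local"))
  Q <- length(fit$personal)
  if (Q < 2) {
    one <- matrix(1, 1, 1, dimnames = list(fit$personal, fit$personal))
    return(list(mean = one, q05 = one, q95 = one))
  }
  u <- fit$draws$u
  ndraw <- nrow(u)
  Cs <- array(0, c(ndraw, Q, Q))
  for (d in seq_len(ndraw)) {
    L <- .chol_from_u(u[d, ], Q)
    Cs[d, , ] <- L %*% t(L)
  }
  dn <- list(fit$personal, fit$personal)
  list(mean = matrix(apply(Cs, c(2, 3), mean), Q, dimnames = dn),
       q05 = matrix(apply(Cs, c(2, 3), quantile, 0.05), Q, dimnames = dn),
       q95 = matrix(apply(Cs, c(2, 3), quantile, 0.95), Q, dimnames = dn))
}

# Per-draw Cholesky factors of C for a local fit (list over draws).
.chol_draws <- function(fit) {
  Q <- length(fit$personal)
  if (Q < 2) return(NULL)
  lapply(seq_len(nrow(fit$draws$u)),
         function(d) .chol_from_u(fit$draws$u[d, ], Q))
}
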