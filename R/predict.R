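#' AR(1)-adjusted expectation
#'
#' Successive observations of a subject are serially correlated: the expected
#' value at time \eqn{t} is shifted by \eqn{\rho} times the previous
#' observation's residual, \eqn{\mu_t + \rho (y_{t-1} - \mu_{t-1})}.
#'
#' @param mu_t expected value at the current time.
#' @param mu_prev expected value at the previous time.
#' @param y_prev observed value at the previous time.
#' @param rho AR(1) coefficient, |rho| < 1.
#' @return the adjusted expectation (vectorized).
#' @examples
#' ar1_expected(2, 2, 3, 0.5)  # 2.5
#' @export
ar1_expected <- function(mu_t, mu_prev, y_prev, rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  mu_t + rho * (y_prev - mu_prev)
}

#' Normalized root mean squared error
#'
#' \eqn{\mathrm{NRMSE} = \sqrt{\frac{1}{n}\sum_j (\hat y_j - y_j)^2} / \bar y}.
#' Normalization by the mean observed level makes errors of differently
#' scaled responses comparable. The network-level error is the unweighted
#' mean of the per-response values.
#'
#' @param predicted predicted values (posterior predictive means).
#' @param observed observed values.
#' @param ybar normalizer; defaults to `mean(observed)`.
#' @return scalar NRMSE.
#' @examples
#' nrmse(c(3, 3, 3), c(2, 2, 2))        # 0.5
#' network_nrmse(c(0.1, 0.3))           # 0.2
#' @export
nrmse <- function(predicted, observed, ybar = mean(observed)) {
  if (length(predicted) != length(observed))
    stop("'predicted' and 'observed' must have equal length")
  if (!length(observed)) stop("empty vectors")
  if (ybar == 0) stop("normalizer ybar must be nonzero")
  sqrt(mean((predicted - observed)^2)) / ybar
}

#' @rdname nrmse
#' @param per_response vector of per-response NRMSE values.
#' @export
network_nrmse <- function(per_response) {
  if (!length(per_response)) stop("empty vector")
  mean(per_response)
}

# Evenly spaced draw indices for prediction-time thinning.
.draw_index <- function(ndraw, n_draws) {
  if (n_draws >= ndraw) return(seq_len(ndraw))
  unique(round(seq(1, ndraw, length.out = n_draws)))
}

# Ancestral sampling through one local distribution. Roots (predictor values,
# posterior parameter draws) are populated first; values propagate to the
# linear predictor, the AR(1) adjustment, and finally the observation family.
.sample_local <- function(local, newdata, n_draws, personal, use_ar) {
  xcols <- setdiff(local$predictors, "(Intercept)")
  miss <- setdiff(xcols, names(newdata))
  if (length(miss)) stop("newdata lacks predictors: ", paste(miss, collapse = ", "))
  nd <- newdata[order(newdata$subject_id, newdata$week), , drop = FALSE]
  N <- nrow(nd)
  X <- cbind(`(Intercept)` = 1, as.matrix(nd[xcols]))
  Z <- X[, local$personal, drop = FALSE]
  subj <- match(as.character(nd$subject_id), local$subjects)
  unknown <- is.na(subj)
  tix <- match(nd$week, sort(unique(nd$week)))
  key <- paste(nd$subject_id, tix); prev <- match(paste(nd$subject_id, tix - 1L), key)

  yobs <- if (local$response %in% names(nd)) nd[[local$response]] else rep(NA_real_, N)
  arf <- local$ar1 & use_ar & !is.na(prev) & !is.na(yobs[ifelse(is.na(prev), 1L, prev)])
  y_prev <- ifelse(arf, yobs[ifelse(is.na(prev), 1L, prev)], 0)
  prev[is.na(prev)] <- 1L

  idx <- .draw_index(nrow(local$draws$beta), n_draws)
  nd_draws <- length(idx)
  mu_mat <- matrix(0, N, nd_draws)
  y_rep <- matrix(0, N, nd_draws)
  for (di in seq_along(idx)) {
    d <- idx[di]
    beta_d <- local$draws$beta[d, ]
    mu <- as.numeric(X %*% beta_d)
    if (personal) {
      bd <- matrix(local$draws$b[d, , ], ncol = length(local$personal))
      bk <- matrix(0, N, length(local$personal))
      bk[!unknown, ] <- bd[subj[!unknown], , drop = FALSE]
      mu <- mu + rowSums(Z * bk)
    }
    mu_adj <- mu
    if (local$ar1 && any(arf)) {
      rho_d <- local$draws$rho[d]
      mu_adj <- ifelse(arf, ar1_expected(mu, mu[prev], y_prev, rho_d), mu)
    }
    disp <- if (length(local$draws$dispersion) > 1)
      local$draws$dispersion[d] else local$draws$dispersion
    y_rep[, di] <- if (local$family == "gamma") {
      rgamma(N, shape = disp, rate = disp / pmax(mu_adj, 1e-6))
    } else {
      rnorm(N, mu_adj, disp)
    }
    mu_mat[, di] <- mu_adj
  }
  list(nd = nd, y_rep = y_rep, mu = mu_mat, arf = arf, unknown = unknown,
       order = order(order(newdata$subject_id, newdata$week)))
}

#' Predict blood-concentration responses by ancestral sampling
#'
#' For each retained posterior draw, evaluates the linear predictor with that
#' draw's general and personal coefficients, applies the AR(1) adjustment
#' where the previous week's observation is available in `newdata`, and draws
#' from the observation family. Subjects unseen at fit time fall back to the
#' population-level prediction (b = 0) and are flagged.
#'
#' @param object a fitted [mebn()] network.
#' @param newdata long-format table with predictor columns on the scale used
#'   at fit time (see `standardized`); response columns, when present, serve
#'   as AR(1) inputs for the following week.
#' @param responses which responses to predict; default all.
#' @param n_draws posterior draws to propagate.
#' @param seed RNG seed; identical seed and inputs reproduce results exactly.
#' @param personal use subject-specific effects where the subject is known.
#' @param use_ar apply the AR(1) adjustment where an input is available.
#' @param standardized set `FALSE` if `newdata` is on the raw predictor scale
#'   and should be put through the stored standardization transform.
#' @param ... unused.
#' @return a `mebn_pred` data frame: subject, week, response, posterior
#'   predictive mean, central 90% interval, and flags `ar_used`,
#'   `personal_used`; full draws in `attr(, "draws")`.
#' @export
predict.mebn <- function(object, newdata = object$data, responses = NULL,
                         n_draws = 200, seed = 1, personal = TRUE,
                         use_ar = TRUE, standardized = TRUE, ...) {
  if (is.null(newdata)) stop("newdata required (fit stores no data)")
  if (!standardized) {
    if (is.null(object$transform))
      stop("no stored transform; supply standardized newdata")
    newdata <- apply_transform(newdata, object$transform)
  }
  responses <- if (is.null(responses)) object$spec$responses else responses
  set.seed(as.integer(seed))
  out <- list(); draws <- list()
  for (r in responses) {
    sl <- .sample_local(object$locals[[r]], newdata, n_draws, personal, use_ar)
    res <- data.frame(subject_id = sl$nd$subject_id, week = sl$nd$week,
                      response = r,
                      mean = rowMeans(sl$y_rep),
                      q05 = apply(sl$y_rep, 1, quantile, 0.05),
                      q95 = apply(sl$y_rep, 1, quantile, 0.95),
                      mu_mean = rowMeans(sl$mu),
                      ar_used = sl$arf, personal_used = personal & !sl$unknown,
                      stringsAsFactors = FALSE)
    out[[r]] <- res
    draws[[r]] <- sl$y_rep
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, draws = draws, class = c("mebn_pred", "data.frame"))
}

#' Posterior predictive check
#'
#' Feeds the original inputs back through ancestral sampling and compares
#' summary statistics of replicated data with the observed data, per
#' response: a statistic outside the central 95% of its replicated
#' distribution flags misfit.
#'
#' @param fit a fitted [mebn()] network.
#' @param data table to check against; defaults to the training table.
#' @param n_draws replicated datasets to draw.
#' @param seed RNG seed.
#' @return class `mebn_ppc`: data frame with columns response, stat,
#'   observed, rep_mean, rep_q025, rep_q975, inside. The replicated draws per
#'   response are attached as `attr(, "replicates")` for density overlays.
#' @export
ppc <- function(fit, data = fit$data, n_draws = 200, seed = 1) {
  stopifnot(inherits(fit, "mebn"))
  if (is.null(data) || !nrow(data)) stop("empty table")
  skew <- function(x) {
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    mean((x - m)^3) / s^3
  }
  stats_fns <- list(mean = mean, sd = stats::sd, q10 = function(x) quantile(x, .1),
                    q90 = function(x) quantile(x, .9), skewness = skew)
  pred <- predict(fit, newdata = data, n_draws = n_draws, seed = seed)
  reps <- attr(pred, "draws")
  rows <- list()
  for (r in fit$spec$responses) {
    obs <- data[order(data$subject_id, data$week), ][[r]]
    keep <- !is.na(obs)
    for (sn in names(stats_fns)) {
      f <- stats_fns[[sn]]
      rep_stat <- apply(reps[[r]][keep, , drop = FALSE], 2, f)
      o <- f(obs[keep])
      lo <- quantile(rep_stat, 0.025); hi <- quantile(rep_stat, 0.975)
      rows[[length(rows) + 1L]] <- data.frame(
        response = r, stat = sn, observed = o, rep_mean = mean(rep_stat),
        rep_q025 = lo, rep_q975 = hi, inside = o >= lo & o <= hi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, replicates = reps, class = c("mebn_ppc", "data.frame"))
}

#' In-sample metric report
#'
#' Per-response NRMSE of posterior predictive means against observations,
#' plus the network-level mean.
#'
#' @param fit a fitted [mebn()] network.
#' @param data evaluation table (default: training data).
#' @param ... passed to [predict.mebn()].
#' @return a list with `per_response` (data frame response, nrmse, ybar, n)
#'   and `network` (scalar mean NRMSE).
#' @export
metric_report <- function(fit, data = fit$data, ...) {
  pred <- predict(fit, newdata = data, ...)
  per <- lapply(fit$spec$responses, function(r) {
    p <- pred[pred$response == r, ]
    key <- paste(data$subject_id, data$week)
    obs <- data[[r]][match(paste(p$subject_id, p$week), key)]
    keep <- !is.na(obs)
    data.frame(response = r,
               nrmse = nrmse(p$mean[keep], obs[keep]),
               ybar = mean(obs[keep]), n = sum(keep),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_response = per, network = network_nrmse(per$nrmse))
}
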