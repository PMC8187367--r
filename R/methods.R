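#' @export
print.mebn_local <- function(x, ...) {
  cat(sprintf("Local mixed-effect posterior for '%s' (%s family%s, %s prior)\n",
              x$response, x$family, if (x$ar1) ", AR(1)" else "",
              x$prior$kind))
  cat(sprintf("  %d general effect(s), %d personal column(s), %d subject(s), %s draws\n",
              length(x$predictors), length(x$personal), length(x$subjects),
              nrow(x$draws$beta)))
  if (!is.null(x$diagnostics$rhat)) {
    worst <- suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))
    cat(sprintf("  max R-hat %.3f, min ESS %.0f\n", worst,
                suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE))))
  }
  invisible(x)
}

#' @export
coef.mebn_local <- function(object, ...) {
  colMeans(object$draws$beta)
}

#' @export
summary.mebn_local <- function(object, prob = 0.9, ...) {
  a <- (1 - prob) / 2
  beta <- object$draws$beta
  out <- data.frame(
    predictor = colnames(beta),
    mean = colMeans(beta),
    sd = apply(beta, 2, stats::sd),
    lo = apply(beta, 2, quantile, a),
    hi = apply(beta, 2, quantile, 1 - a),
    sigma_b = NA_real_, stringsAsFactors = FALSE)
  sb <- colMeans(object$draws$sigma_b)
  out$sigma_b[match(names(sb), out$predictor)] <- sb
  rownames(out) <- NULL
  attr(out, "rho") <- if (object$ar1) mean(object$draws$rho)
  attr(out, "dispersion") <- mean(object$draws$dispersion)
  out
}

#' @export
print.mebn <- function(x, ...) {
  print(x$spec)
  cat(sprintf("Fitted network posterior: %d local distribution(s)",
              length(x$locals)))
  if (!is.null(x$data)) cat(sprintf(", %d training rows", nrow(x$data)))
  cat("\n")
  invisible(x)
}

#' Posterior-mean general effects of a fitted network
#'
#' @param object a fitted [mebn()].
#' @param ... unused.
#' @return matrix responses x predictors (including the intercept) of
#'   posterior means of the general coefficients.
#' @export
coef.mebn <- function(object, ...) {
  t(vapply(object$locals, coef, numeric(length(object$spec$predictors) + 1L)))
}

#' @export
summary.mebn <- function(object, ...) {
  tabs <- lapply(object$spec$responses, function(r) {
    s <- summary(object$locals[[r]], ...)
    s$response <- r
    s
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("summary.mebn", "data.frame")
  out
}

#' @export
print.summary.mebn <- function(x, ...) {
  cat("Posterior summaries of general effects (mean, 90% CI, sigma_b):\n")
  print.data.frame(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
residuals.mebn <- function(object, n_draws = 200, seed = 1, ...) {
  if (is.null(object$data)) stop("fit stores no training data")
  pred <- predict(object, n_draws = n_draws, seed = seed, ...)
  data <- object$data
  key <- paste(data$subject_id, data$week)
  sapply(object$spec$responses, function(r) {
    p <- pred[pred$response == r, ]
    obs <- data[[r]][match(paste(p$subject_id, p$week), key)]
    obs - p$mean
  })
}

#' Posterior predictive replicates of the training responses
#'
#' @param object a fitted [mebn()].
#' @param nsim number of replicated datasets.
#' @param seed RNG seed.
#' @param ... passed to [predict.mebn()].
#' @return a list of `nsim` data frames shaped like the training table's
#'   response columns.
#' @export
simulate.mebn <- function(object, nsim = 1, seed = 1, ...) {
  if (is.null(object$data)) stop("fit stores no training data")
  pred <- predict(object, n_draws = nsim, seed = seed, ...)
  draws <- attr(pred, "draws")
  nd <- object$data[order(object$data$subject_id, object$data$week), ]
  lapply(seq_len(min(nsim, ncol(draws[[1]]))), function(i) {
    out <- nd[c("subject_id", "week")]
    for (r in names(draws)) out[[r]] <- draws[[r]][, i]
    out
  })
}

#' Caterpillar plot of general effects
#'
#' Base-graphics display of posterior means and 90% intervals of the general
#' coefficients, one panel column per response.
#'
#' @param x a fitted [mebn()].
#' @param response which response; default first.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mebn <- function(x, response = x$spec$responses[1], ...) {
  s <- summary(x$locals[[response]])
  s <- s[s$predictor != "(Intercept)", ]
  n <- nrow(s)
  graphics::plot(s$mean, seq_len(n), xlim = range(s$lo, s$hi), yaxt = "n",
                 xlab = expression(beta), ylab = "",
                 main = paste("General effects on", response), pch = 19, ...)
  graphics::segments(s$lo, seq_len(n), s$hi, seq_len(n))
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = seq_len(n), labels = s$predictor, las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
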