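#' @importFrom stats quantile rnorm rgamma rbeta rbinom sd setNames coef
#'   predict simulate residuals median var update
NULL

# Canonical hash of a study table, used as fit provenance so that locals
# assembled into one network are guaranteed to come from the same data.
.data_hash <- function(data) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  ord <- do.call(order, unname(as.list(data[, intersect(c("subject_id", "week"),
                                                        names(data)), drop = FALSE])))
  saveRDS(lapply(data[ord, , drop = FALSE], function(x)
    if (is.numeric(x)) signif(x, 12) else as.character(x)), f, version = 2)
  unname(tools::md5sum(f))
}

# Row ordering, design matrices and AR(1) bookkeeping for one response.
# AR inputs come only from a subject's immediately preceding week on the
# common grid; if that row is absent (a gap, e.g. a held-out CV cell) the AR
# term is dropped for that observation.
.prepare_local_data <- function(data, spec, response) {
  need <- c("subject_id", "week", spec$predictors, response)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("columns missing from data: ", paste(miss, collapse = ", "))
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (!nrow(data)) stop("no observations for response '", response, "'")
  data <- data[order(data$subject_id, data$week), , drop = FALSE]
  if (anyDuplicated(data[c("subject_id", "week")]))
    stop("duplicate (subject_id, week) rows")
  subjects <- unique(as.character(data$subject_id))
  subj <- match(as.character(data$subject_id), subjects)
  grid <- sort(unique(data$week))
  tix <- match(data$week, grid)
  N <- nrow(data)

  X <- cbind(`(Intercept)` = 1, as.matrix(data[spec$predictors]))
  zcols <- c(if (spec$personal_intercept) "(Intercept)", spec$personal)
  Z <- X[, zcols, drop = FALSE]

  y <- data[[response]]
  fam <- spec$families[[response]]
  if (fam == "gamma" && any(y <= 0))
    stop("gamma-family response '", response, "' must be strictly positive")

  key <- paste(subj, tix)
  prev_key <- paste(subj, tix - 1L)
  prev <- match(prev_key, key)
  arf <- as.numeric(spec$ar1 & !is.na(prev) & tix > 1L)
  y_prev <- ifelse(arf > 0, y[ifelse(is.na(prev), 1L, prev)], 0)
  prev[is.na(prev)] <- seq_len(N)[is.na(prev)]  # self-pointer, masked by arf

  list(data = data, X = X, Z = Z, y = y, y_prev = y_prev, prev = prev,
       arf = arf, subj = subj, subjects = subjects, grid = grid, tix = tix,
       family = fam, N = N, S = length(subjects),
       P = ncol(X), Q = ncol(Z), zcols = zcols)
}

#' Fit one local distribution of the network
#'
#' Estimates, by MCMC, the mixed-effect regression of a single response on the
#' network's predictors: general coefficients \eqn{\beta}, correlated personal
#' slopes \eqn{b_k = T L z_k} in the non-centered parameterization (with
#' \eqn{T = diag(\sigma_b)} and \eqn{L} the Cholesky factor of the effect
#' correlation matrix \eqn{C}, given an LKJ(\eqn{\eta}) prior), the AR(1)
#' coefficient \eqn{\rho} for successive observations, and the family
#' parameter (Gamma shape \eqn{\alpha} or Normal residual sd).
#'
#' The identity-link Gamma likelihood requires a positive mean; the sampler
#' evaluates the likelihood with the mean soft-bounded below at 1e-6.
#'
#' @param data long-format study table with standardized predictors.
#' @param spec a [mebn_spec()].
#' @param response which response column to fit.
#' @param chains,adapt,burn,iter,thin MCMC settings (per chain).
#' @param seed integer seed; chains use derived RNG seeds.
#' @param lkj_eta shape of the LKJ prior on the personal-effect correlations.
#' @param store_z keep the standard-normal latents \eqn{z_k} in the draws.
#' @param baseline_outcome model the first-week responses as outcomes
#'   (default). With `FALSE` they contribute no likelihood and serve only as
#'   AR(1) inputs for the following week.
#' @param quiet suppress sampler progress.
#' @return an object of class `mebn_local` carrying parameter draws,
#'   convergence diagnostics (split into R-hat and effective sample size),
#'   and fit provenance.
#' @export
mebn_local <- function(data, spec, response, chains = 2, adapt = 500,
                       burn = 500, iter = 1000, thin = 1, seed = 1,
                       lkj_eta = 2, store_z = FALSE, baseline_outcome = TRUE,
                       quiet = TRUE) {
  stopifnot(inherits(spec, "mebn_spec"))
  if (!response %in% spec$responses) stop("'", response, "' is not in the spec")
  pd <- .prepare_local_data(data, spec, response)
  if (pd$P < 2) stop("at least one predictor is required")
  .check_standardized(pd$X[, -1, drop = FALSE])

  prior <- spec$priors[[response]]
  y_fit <- pd$y
  if (!baseline_outcome) {
    # first-week values stay available as AR inputs (y_prev) but are treated
    # as unobserved nodes, contributing no likelihood
    y_fit[pd$tix == 1L] <- NA_real_
  }
  code <- .mebn_model_code(pd$family, prior$kind, pd$Q, spec$ar1)
  jd <- list(y = y_fit, y_prev = pd$y_prev, X = pd$X, Z = pd$Z,
             subj = pd$subj, prev = pd$prev, arf = pd$arf,
             N = pd$N, S = pd$S, P = pd$P, Q = pd$Q,
             scale_int = prior$intercept_scale)
  if (prior$kind == "vague") {
    jd$scale_slope <- prior$slope_scale
  } else {
    jd$tau0 <- prior$tau0; jd$nu <- prior$nu; jd$s2 <- prior$slab_scale^2
  }
  if (pd$Q >= 2) {
    pr <- .lkj_pairs(pd$Q, lkj_eta)
    jd$n_pair <- pr$n_pair; jd$idx <- pr$idx; jd$a_lkj <- pr$a
  }
  if (!spec$ar1) { jd$arf <- NULL; jd$y_prev <- NULL; jd$prev <- NULL }

  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) %% 100000L) * 1000L + ch))
  monitors <- c("beta", "sigma_b", "b",
                if (pd$Q >= 2) "u",
                if (store_z) "z",
                if (spec$ar1) "rho",
                if (pd$family == "gamma") "alpha" else "sigma_eps")
  jm <- tryCatch(
    rjags::jags.model(textConnection(code), data = jd, inits = inits,
                      n.chains = chains, n.adapt = adapt, quiet = quiet),
    error = function(e) stop("sampler failed for response '", response,
                             "': ", conditionMessage(e)))
  update(jm, burn, progress.bar = if (quiet) "none" else "text")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                              progress.bar = if (quiet) "none" else "text")

  mats <- lapply(samp, as.matrix)
  m <- do.call(rbind, mats)
  chain_id <- rep(seq_len(chains), each = nrow(mats[[1]]))
  ndraw <- nrow(m)

  beta <- m[, paste0("beta[", seq_len(pd$P), "]"), drop = FALSE]
  colnames(beta) <- colnames(pd$X)
  sigma_b <- m[, paste0("sigma_b[", seq_len(pd$Q), "]"), drop = FALSE]
  colnames(sigma_b) <- pd$zcols
  b <- array(0, c(ndraw, pd$S, pd$Q),
             dimnames = list(NULL, pd$subjects, pd$zcols))
  for (k in seq_len(pd$S)) for (j in seq_len(pd$Q))
    b[, k, j] <- m[, paste0("b[", k, ",", j, "]")]
  u <- if (pd$Q >= 2) {
    nm <- if (jd$n_pair == 1) "u" else paste0("u[", seq_len(jd$n_pair), "]")
    m[, nm, drop = FALSE]
  }
  z <- if (store_z) {
    zz <- array(0, c(ndraw, pd$S, pd$Q),
                dimnames = list(NULL, pd$subjects, pd$zcols))
    for (k in seq_len(pd$S)) for (j in seq_len(pd$Q))
      zz[, k, j] <- m[, paste0("z[", k, ",", j, "]")]
    zz
  }
  disp_name <- if (pd$family == "gamma") "alpha" else "sigma_eps"
  draws <- list(beta = beta, sigma_b = sigma_b, b = b, u = u, z = z,
                rho = if (spec$ar1) as.numeric(m[, "rho"]),
                dispersion = as.numeric(m[, disp_name]),
                chain = chain_id)

  scalar_cols <- c(paste0("beta[", seq_len(pd$P), "]"),
                   paste0("sigma_b[", seq_len(pd$Q), "]"),
                   if (spec$ar1) "rho", disp_name)
  sub <- samp[, scalar_cols, drop = FALSE]
  rhat <- if (chains >= 2)
    tryCatch(coda::gelman.diag(sub, multivariate = FALSE,
                               autoburnin = FALSE)$psrf[, 1],
             error = function(e) rep(NA_real_, length(scalar_cols)))
  ess <- coda::effectiveSize(sub)

  structure(list(
    response = response, family = pd$family, prior = prior,
    ar1 = spec$ar1, lkj_eta = lkj_eta,
    predictors = colnames(pd$X), personal = pd$zcols,
    subjects = pd$subjects, grid = pd$grid,
    draws = draws,
    diagnostics = list(rhat = rhat, ess = ess, n_chains = chains,
                       n_iter = iter, adapt = adapt, burn = burn),
    data_hash = .data_hash(data), seed = seed,
    n_obs = pd$N), class = "mebn_local")
}

.check_standardized <- function(X) {
  if (nrow(X) < 30) return(invisible(TRUE))
  mu <- colMeans(X); s <- apply(X, 2, stats::sd)
  off <- abs(mu) > 0.3 | abs(s - 1) > 0.3
  if (any(off))
    warning("predictor column(s) do not look standardized: ",
            paste(colnames(X)[off], collapse = ", "))
  invisible(!any(off))
}

#' Construct a degenerate local posterior from known parameters
#'
#' Builds a `mebn_local` whose "posterior" is a point mass at supplied
#' parameter values, with personal effects composed as \eqn{b_k = T L z_k}.
#' Useful for analysing a known generating process with the same prediction,
#' evaluation, and effect-analysis machinery as a fitted model.
#'
#' @param response response name.
#' @param predictors predictor names (an intercept column is added first).
#' @param personal personal-effect columns (subset of the design columns,
#'   intercept included by listing `"(Intercept)"`).
#' @param subjects subject identifiers.
#' @param family `"normal"` or `"gamma"`.
#' @param beta general coefficients, length `length(predictors) + 1`
#'   (intercept first).
#' @param sigma_b personal-effect standard deviations (length = personal cols).
#' @param C personal-effect correlation matrix (default identity).
#' @param z standard-normal latents, subjects x personal cols (default 0).
#' @param rho AR(1) coefficient, or `NULL` for no serial term.
#' @param dispersion Gamma shape or Normal residual sd.
#' @param grid the shared week grid.
#' @return a `mebn_local` with a single draw.
#' @export
mebn_local_from_params <- function(response, predictors, personal,
                                   subjects, family = "normal",
                                   beta, sigma_b, C = NULL, z = NULL,
                                   rho = NULL, dispersion = 1,
                                   grid = c(0, 4, 8, 12)) {
  xcols <- c("(Intercept)", predictors)
  stopifnot(length(beta) == length(xcols), all(personal %in% xcols),
            family %in% .families)
  Q <- length(personal); S <- length(subjects)
  stopifnot(length(sigma_b) == Q)
  if (is.null(C)) C <- diag(Q)
  stopifnot(nrow(C) == Q, max(abs(diag(C) - 1)) < 1e-8)
  L <- if (Q > 1) t(chol(C)) else matrix(1, 1, 1)
  if (is.null(z)) z <- matrix(0, S, Q)
  b <- t(apply(z, 1, function(zk) compose_personal_effect(sigma_b, L, zk)))
  if (Q == 1) b <- matrix(as.numeric(z) * sigma_b, S, 1)
  barr <- array(b, c(1, S, Q), dimnames = list(NULL, subjects, personal))
  zarr <- array(z, c(1, S, Q), dimnames = list(NULL, subjects, personal))
  u <- if (Q >= 2) {
    # invert the angle construction so draws$u matches C exactly
    uu <- numeric(Q * (Q - 1) / 2); t <- 0L
    for (j in 2:Q) {
      sp <- 1
      for (m in seq_len(j - 1)) {
        t <- t + 1L
        x <- L[j, m] / sp
        uu[t] <- (x + 1) / 2
        sp <- sp * sqrt(max(1 - x^2, 0))
      }
    }
    matrix(uu, 1)
  }
  structure(list(
    response = response, family = family,
    prior = prior_vague(), ar1 = !is.null(rho), lkj_eta = NA_real_,
    predictors = xcols, personal = personal, subjects = subjects,
    grid = grid,
    draws = list(beta = matrix(beta, 1, dimnames = list(NULL, xcols)),
                 sigma_b = matrix(sigma_b, 1, dimnames = list(NULL, personal)),
                 b = barr, u = u, z = zarr,
                 rho = if (!is.null(rho)) rho,
                 dispersion = dispersion, chain = 1L),
    diagnostics = list(rhat = NULL, ess = NULL, n_chains = 1, n_iter = 1),
    data_hash = NA_character_, seed = NA_integer_,
    n_obs = NA_integer_), class = "mebn_local")
}

#' Assemble local posteriors into a network posterior
#'
#' Collects independently estimated local distributions into one joint
#' Bayesian network object. All locals must cover exactly the spec's
#' responses and must have been fitted on the same study table (checked via
#' the stored data hash).
#'
#' @param locals list of [mebn_local()] fits.
#' @param spec the shared [mebn_spec()].
#' @param data optionally, the training table to store with the network.
#' @return an object of class `mebn`.
#' @export
mebn_assemble <- function(locals, spec, data = NULL) {
  stopifnot(inherits(spec, "mebn_spec"))
  got <- vapply(locals, `[[`, "", "response")
  names(locals) <- got
  miss <- setdiff(spec$responses, got)
  if (length(miss))
    stop("missing local posterior(s) for response(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(got, spec$responses)
  if (length(extra))
    stop("local posterior(s) not in spec: ", paste(extra, collapse = ", "))
  hashes <- vapply(locals, `[[`, "", "data_hash")
  known <- hashes[!is.na(hashes)]
  if (length(unique(known)) > 1)
    stop("local posteriors were fitted on different data (hash mismatch)")
  structure(list(spec = spec, locals = locals[spec$responses],
                 data = data,
                 data_hash = if (length(known)) known[[1]] else NA_character_),
            class = "mebn")
}

#' Fit a mixed-effect Bayesian network
#'
#' The main fitting function: estimates one local mixed-effect regression per
#' response (see [mebn_local()]) and assembles them into a joint network
#' posterior. Local distributions are conditionally independent given the
#' bipartite structure, so the joint posterior is their product.
#'
#' @param data long-format study table: one row per (subject, week), with
#'   standardized predictor columns and response columns.
#' @param spec a [mebn_spec()].
#' @param responses which responses to fit; default all in the spec.
#' @param transform optional `mebn_transform` from [standardize_predictors()],
#'   stored for prediction-time scale handling.
#' @param ... sampler settings passed to [mebn_local()].
#' @param seed integer master seed.
#' @return an object of class `mebn` with methods `print`, `summary`, `coef`,
#'   `predict`, `simulate`, and `residuals`.
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(s = 20, p = 3, v = 1), seed = 1)
#' spec <- attr(sim, "spec")
#' fit <- mebn(sim$data, spec, iter = 200, adapt = 200, burn = 100)
#' coef(fit)
#' }
#' @export
mebn <- function(data, spec, responses = spec$responses, transform = NULL,
                 ..., seed = 1) {
  locals <- vector("list", length(responses))
  for (i in seq_along(responses)) {
    locals[[i]] <- mebn_local(data, spec, responses[[i]],
                              seed = seed + i - 1L, ...)
  }
  net <- mebn_assemble(locals, .spec_subset(spec, responses), data = data)
  net$transform <- transform
  net$seed <- seed
  net
}

# Restrict a spec to a subset of responses (used when fitting fewer locals).
.spec_subset <- function(spec, responses) {
  if (identical(responses, spec$responses)) return(spec)
  mebn_spec(responses, spec$predictors, spec$personal,
            families = unlist(spec$families[responses]),
            priors = spec$priors[responses], ar1 = spec$ar1,
            personal_intercept = spec$personal_intercept)
}
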