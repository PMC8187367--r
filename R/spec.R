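#' Global shrinkage scale for the regularized horseshoe prior
#'
#' Computes the prior guess \eqn{\tau_0} for the global shrinkage parameter of
#' the regularized horseshoe from the expected number of nonzero coefficients:
#' \deqn{\tau_0 = \frac{p_0}{p - p_0} \frac{\sigma}{\sqrt{n}},}
#' where \eqn{p} is the number of candidate predictors, \eqn{p_0} the number
#' expected to carry signal, \eqn{\sigma} a residual-scale proxy (1 on the
#' standardized scale), and \eqn{n} the total number of observations.
#'
#' @param p0 expected number of nonzero coefficients (0 < p0 < p).
#' @param p total number of candidate predictors.
#' @param sigma residual standard-deviation proxy; defaults to 1, appropriate
#'   when predictors and response are on the standardized scale.
#' @param n total number of observations used in the fit.
#' @return the scalar \eqn{\tau_0}.
#' @examples
#' rhs_tau0(7, 22, 1, 424)  # ~ 0.023
#' @export
rhs_tau0 <- function(p0, p, sigma = 1, n) {
  if (!is.numeric(p0) || !is.numeric(p) || p0 <= 0 || p0 >= p)
    stop("'p0' must satisfy 0 < p0 < p")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (n < 1) stop("'n' must be at least 1")
  p0 / (p - p0) * sigma / sqrt(n)
}

#' Prior specifications for the general effects
#'
#' `prior_vague()` gives independent Cauchy priors: Cauchy(0, `intercept_scale`)
#' for the intercept and Cauchy(0, `slope_scale`) for each slope.
#' `prior_rhs()` gives the regularized horseshoe: per-coefficient half-Cauchy
#' local scales, a global scale with half-Cauchy(0, \eqn{\tau_0}) prior where
#' \eqn{\tau_0} comes from [rhs_tau0()], and an inverse-Gamma slab
#' \eqn{c^2 \sim \mathrm{Inv\text{-}Gamma}(\nu/2, \nu s^2/2)} that caps the
#' largest coefficients. The intercept keeps the vague Cauchy prior in both.
#'
#' @param intercept_scale,slope_scale Cauchy scales of the vague prior.
#' @param p0 expected number of nonzero slopes.
#' @param p number of candidate slopes.
#' @param n total number of observations the model will see.
#' @param sigma residual-sd proxy entering \eqn{\tau_0}; default 1.
#' @param nu slab degrees of freedom; the suggested value is 1, increasing it
#'   can ease computational problems.
#' @param slab_scale slab scale \eqn{s}; default 2 (weakly informative).
#' @return an object of class `mebn_prior`.
#' @export
prior_vague <- function(intercept_scale = 10, slope_scale = 2.5) {
  stopifnot(intercept_scale > 0, slope_scale > 0)
  structure(list(kind = "vague", intercept_scale = intercept_scale,
                 slope_scale = slope_scale),
            class = "mebn_prior")
}

#' @rdname prior_vague
#' @export
prior_rhs <- function(p0, p, n, sigma = 1, nu = 1, slab_scale = 2,
                      intercept_scale = 10) {
  tau0 <- rhs_tau0(p0, p, sigma, n)
  stopifnot(nu > 0, slab_scale > 0, intercept_scale > 0)
  structure(list(kind = "rhs", p0 = p0, p = p, n = n, sigma = sigma,
                 nu = nu, slab_scale = slab_scale, tau0 = tau0,
                 intercept_scale = intercept_scale),
            class = "mebn_prior")
}

#' @export
print.mebn_prior <- function(x, ...) {
  if (x$kind == "vague") {
    cat(sprintf("Vague prior: intercept ~ Cauchy(0, %g), slopes ~ Cauchy(0, %g)\n",
                x$intercept_scale, x$slope_scale))
  } else {
    cat(sprintf(paste0("Regularized horseshoe: p0 = %g of p = %g, tau0 = %.4g, ",
                       "slab s = %g (nu = %g)\n"),
                x$p0, x$p, x$tau0, x$slab_scale, x$nu))
  }
  invisible(x)
}

.families <- c("normal", "gamma")

#' Bipartite network specification
#'
#' Declares the structure of a mixed-effect Bayesian network: a fully
#' connected bipartite graph from `predictors` to `responses` (every other
#' structure has prior probability zero), the subset of predictors whose
#' effects carry subject-level random slopes, the observation family of each
#' response, its prior regime, and whether the AR(1) serial-correlation term
#' is included. Edge count is always `length(responses) * length(predictors)`.
#'
#' @param responses character vector of response column names.
#' @param predictors character vector of predictor column names.
#' @param personal predictors receiving personal (random) effects; defaults to
#'   all predictors, mirroring identical general/personal model matrices.
#' @param families a single family or named vector per response;
#'   `"normal"` or `"gamma"` (identity link in both cases).
#' @param priors a single [prior_vague()]/[prior_rhs()] object or a named list
#'   per response.
#' @param ar1 logical; include the AR(1) residual-correlation term.
#' @param personal_intercept logical; give each subject a personal baseline
#'   (an intercept column in the personal design matrix). Default `TRUE`.
#' @return an object of class `mebn_spec`.
#' @examples
#' spec <- mebn_spec(c("hdl", "insulin"), c("energy", "pufa"),
#'                   families = c(hdl = "gamma", insulin = "normal"))
#' n_edges(spec)  # 4
#' @export
mebn_spec <- function(responses, predictors, personal = predictors,
                      families = "gamma", priors = prior_vague(),
                      ar1 = TRUE, personal_intercept = TRUE) {
  if (anyDuplicated(responses)) stop("duplicate response names")
  if (anyDuplicated(predictors)) stop("duplicate predictor names")
  if (length(intersect(responses, predictors)))
    stop("responses and predictors must be disjoint")
  bad <- setdiff(personal, predictors)
  if (length(bad))
    stop("personal predictors not among predictors: ", paste(bad, collapse = ", "))

  families <- .recycle_named(families, responses, "families")
  ok <- vapply(families, function(f) f %in% .families, logical(1))
  if (!all(ok))
    stop("unknown family: ", paste(unlist(families[!ok]), collapse = ", "))
  if (inherits(priors, "mebn_prior")) {
    priors <- stats::setNames(rep(list(priors), length(responses)), responses)
  } else {
    priors <- .recycle_named(priors, responses, "priors", atomic = FALSE)
    ok <- vapply(priors, inherits, logical(1), "mebn_prior")
    if (!all(ok)) stop("priors must be mebn_prior objects")
  }
  structure(list(responses = responses, predictors = predictors,
                 personal = personal,
                 families = vapply(families, identity, character(1)),
                 priors = priors, ar1 = isTRUE(ar1),
                 personal_intercept = isTRUE(personal_intercept)),
            class = "mebn_spec")
}

.recycle_named <- function(x, names, what, atomic = TRUE) {
  if (length(x) == 1 && is.null(names(x))) {
    out <- stats::setNames(rep(if (atomic) x else list(x[[1]]), length(names)), names)
    return(as.list(out))
  }
  if (is.null(names(x)) && length(x) == length(names)) {
    return(stats::setNames(as.list(x), names))
  }
  miss <- setdiff(names, names(x))
  if (length(miss))
    stop(what, " missing for response(s): ", paste(miss, collapse = ", "))
  as.list(x)[names]
}

#' Number of candidate effects (edges) in a network specification
#' @param spec a [mebn_spec()] object.
#' @return integer edge count, responses x predictors.
#' @export
n_edges <- function(spec) {
  stopifnot(inherits(spec, "mebn_spec"))
  length(spec$responses) * length(spec$predictors)
}

#' @export
print.mebn_spec <- function(x, ...) {
  cat(sprintf("Mixed-effect Bayesian network spec: %d response(s) x %d predictor(s) = %d candidate effects\n",
              length(x$responses), length(x$predictors), n_edges(x)))
  cat("  responses: ", paste(x$responses, collapse = ", "), "\n", sep = "")
  cat("  families:  ", paste(unique(unname(x$families)), collapse = ", "), "\n", sep = "")
  cat("  personal predictors: ", length(x$personal),
      if (x$personal_intercept) " (+ personal intercept)" else "", "\n", sep = "")
  cat("  priors: ", paste(unique(vapply(x$priors, `[[`, "", "kind")), collapse = ", "),
      "; AR(1): ", x$ar1, "\n", sep = "")
  invisible(x)
}

#' Serialize / read a network specification as YAML
#'
#' Round-trip safe: `read_spec_yaml(write_spec_yaml(spec, f))` reproduces the
#' specification exactly.
#'
#' @param spec a [mebn_spec()] object.
#' @param file path to a YAML file.
#' @return `write_spec_yaml` returns `file` invisibly; `read_spec_yaml`
#'   returns the `mebn_spec`.
#' @export
write_spec_yaml <- function(spec, file) {
  stopifnot(inherits(spec, "mebn_spec"))
  pr <- lapply(spec$priors, function(p) p[setdiff(names(p), NULL)])
  obj <- list(responses = spec$responses, predictors = spec$predictors,
              personal = spec$personal,
              families = as.list(spec$families),
              priors = pr, ar1 = spec$ar1,
              personal_intercept = spec$personal_intercept)
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(file) {
  obj <- yaml::read_yaml(file)
  priors <- lapply(obj$priors, function(p) {
    if (identical(p$kind, "vague")) {
      prior_vague(p$intercept_scale, p$slope_scale)
    } else {
      prior_rhs(p$p0, p$p, p$n, p$sigma, p$nu, p$slab_scale, p$intercept_scale)
    }
  })
  mebn_spec(responses = unlist(obj$responses),
            predictors = unlist(obj$predictors),
            personal = unlist(obj$personal),
            families = unlist(obj$families),
            priors = priors, ar1 = obj$ar1,
            personal_intercept = obj$personal_intercept)
}
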