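#' Configuration of a synthetic longitudinal study
#'
#' Describes the generative model exactly as the network assumes it: s
#' subjects measured on a shared week grid, standardized predictors (optional
#' binary columns emulating sex/medication), per-response general
#' coefficients, correlated subject-level random slopes with covariance
#' \eqn{T C T'}, AR(1) serial residual correlation, and Normal or
#' identity-link Gamma observation noise.
#'
#' @param s number of subjects.
#' @param weeks measurement grid; default `c(0, 4, 8, 12)`.
#' @param p number of predictors (names auto-generated unless given).
#' @param predictors predictor names; overrides `p`.
#' @param binary names (or count) of binary predictors among them.
#' @param v number of responses (names auto-generated unless given).
#' @param responses response names; overrides `v`.
#' @param personal predictors with personal effects; default all.
#' @param personal_intercept subjects get personal baselines; default TRUE.
#' @param beta general coefficients: vector (recycled per response) or
#'   v x (p + 1) matrix, intercept first.
#' @param sigma_b personal-effect sds: vector (recycled) or v x q matrix,
#'   where q counts the personal columns (intercept included when
#'   `personal_intercept`).
#' @param C personal-effect correlation matrix (shared across responses), or
#'   a list of length v.
#' @param rho AR(1) coefficient(s), |rho| < 1; scalar recycled.
#' @param families `"normal"`/`"gamma"` per response (recycled).
#' @param dispersion Gamma shape or Normal residual sd per response
#'   (recycled).
#' @return class `mebn_sim_config`.
#' @export
sim_config <- function(s = 50, weeks = c(0, 4, 8, 12), p = 5,
                       predictors = NULL, binary = character(0),
                       v = 1, responses = NULL,
                       personal = NULL, personal_intercept = TRUE,
                       beta = NULL, sigma_b = 0.5, C = NULL, rho = 0.3,
                       families = "normal", dispersion = 1) {
  if (is.null(predictors)) predictors <- sprintf("x%02d", seq_len(p))
  p <- length(predictors)
  if (is.numeric(binary)) binary <- utils::tail(predictors, binary)
  stopifnot(all(binary %in% predictors))
  if (is.null(responses)) responses <- sprintf("y%d", seq_len(v))
  v <- length(responses)
  if (is.null(personal)) personal <- predictors
  stopifnot(all(personal %in% predictors))
  q <- length(personal) + as.integer(personal_intercept)

  if (is.null(beta)) beta <- c(10, rep(0.5, p))
  B <- if (is.matrix(beta)) beta else matrix(beta, v, p + 1, byrow = TRUE)
  stopifnot(nrow(B) == v, ncol(B) == p + 1)
  SB <- if (is.matrix(sigma_b)) sigma_b else
    matrix(rep_len(sigma_b, q), v, q, byrow = TRUE)
  stopifnot(nrow(SB) == v, ncol(SB) == q, all(SB >= 0))
  if (is.null(C)) C <- diag(q)
  Cs <- if (is.list(C)) C else rep(list(C), v)
  for (Ci in Cs) {
    stopifnot(nrow(Ci) == q, ncol(Ci) == q)
    if (max(abs(diag(Ci) - 1)) > 1e-10) stop("C must have unit diagonal")
    if (max(abs(Ci - t(Ci))) > 1e-10) stop("C must be symmetric")
    ev <- eigen(Ci, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) stop("C must be positive definite")
  }
  rho <- rep_len(rho, v)
  stopifnot(all(abs(rho) < 1))
  families <- rep_len(families, v)
  stopifnot(all(families %in% .families))
  dispersion <- rep_len(dispersion, v)
  stopifnot(all(dispersion > 0))

  structure(list(s = s, weeks = sort(weeks), predictors = predictors,
                 binary = binary, responses = responses, personal = personal,
                 personal_intercept = isTRUE(personal_intercept),
                 beta = B, sigma_b = SB, C = Cs, rho = rho,
                 families = setNames(families, responses),
                 dispersion = setNames(dispersion, responses)),
            class = "mebn_sim_config")
}

#' Simulate a study table from the generative model
#'
#' Predictors are drawn standard normal (binary columns Bernoulli(0.5)), then
#' standardized to exact sample mean 0 / sd 1 so the table satisfies the
#' study-table invariants and the true coefficients apply to the observed
#' design. Per subject and response, random slopes come from
#' \eqn{N(0, T C T')}; observations follow the AR(1) process
#' \eqn{y_t = \mu_t + \rho (y_{t-1} - \mu_{t-1}) + \epsilon_t} with a
#' stationary first time point, under Normal or identity-link Gamma noise.
#' For Gamma responses a nonpositive mean (possible with additive effects) is
#' re-drawn and counted; configurations should keep such violations below
#' 0.1%.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return list of class `mebn_sim`: `data` (long study table), `truth`
#'   (every latent used in generation), and the matching `mebn_spec` as
#'   attribute `spec`.
#' @export
simulate_study <- function(config, seed = 1) {
  stopifnot(inherits(config, "mebn_sim_config"))
  set.seed(as.integer(seed))
  s <- config$s; weeks <- config$weeks; nk <- length(weeks)
  N <- s * nk
  p <- length(config$predictors); v <- length(config$responses)
  subjects <- sprintf("S%03d", seq_len(s))

  Xr <- matrix(rnorm(N * p), N, p, dimnames = list(NULL, config$predictors))
  for (bcol in config$binary) {
    val <- rbinom(s, 1, 0.5)           # constant within subject
    Xr[, bcol] <- rep(val, each = nk)
  }
  data <- data.frame(subject_id = rep(subjects, each = nk),
                     week = rep(weeks, s), stringsAsFactors = FALSE)
  raw <- as.data.frame(Xr)
  std <- standardize_predictors(cbind(data, raw), cols = config$predictors)
  data <- std$data
  X <- cbind(`(Intercept)` = 1, as.matrix(data[config$predictors]))
  zcols <- c(if (config$personal_intercept) "(Intercept)", config$personal)
  Z <- X[, zcols, drop = FALSE]
  q <- ncol(Z)

  truth <- list(config = config, seed = seed, subjects = subjects,
                transform = std$transform, zcols = zcols,
                beta = config$beta, sigma_b = config$sigma_b,
                C = config$C, rho = config$rho,
                dispersion = config$dispersion, b = list(), mu = list(),
                redraws = setNames(integer(v), config$responses))
  subj <- rep(seq_len(s), each = nk)
  tloc <- rep(seq_len(nk), s)

  for (i in seq_len(v)) {
    r <- config$responses[i]
    L <- t(chol(config$C[[i]]))
    Tm <- diag(x = config$sigma_b[i, ], nrow = q)
    zlat <- matrix(rnorm(s * q), q, s)
    b <- t(Tm %*% L %*% zlat)                     # s x q
    truth$b[[r]] <- b
    mu <- as.numeric(X %*% config$beta[i, ] + rowSums(Z * b[subj, , drop = FALSE]))
    truth$mu[[r]] <- mu
    rho <- config$rho[i]; fam <- config$families[[r]]
    disp <- config$dispersion[[r]]
    y <- numeric(N)
    for (rix in seq_len(N)) {
      t0 <- tloc[rix] == 1L
      m <- if (t0) mu[rix] else mu[rix] + rho * (y[rix - 1] - mu[rix - 1])
      if (fam == "normal") {
        sd_t <- if (t0) disp / sqrt(1 - rho^2) else disp
        y[rix] <- rnorm(1, m, sd_t)
      } else {
        # stationary start: deflate the shape so Var matches sigma^2/(1-rho^2)
        a_t <- if (t0) disp * (1 - rho^2) else disp
        if (m <= 0) {  # nonpositive mean under the identity link: floor it,
          truth$redraws[r] <- truth$redraws[r] + 1L  # as the likelihood does
          m <- 1e-6
        }
        y[rix] <- rgamma(1, shape = a_t, rate = a_t / m)
      }
    }
    if (fam == "gamma" && truth$redraws[r] > 0.01 * N)
      stop("gamma-family mean nonpositive for over 1% of observations of '",
           r, "'; the intercept must dominate the effects")
    data[[r]] <- y
  }
  structure(list(data = data, truth = truth),
            spec = mebn_spec(config$responses, config$predictors,
                             personal = config$personal,
                             families = config$families,
                             ar1 = TRUE,
                             personal_intercept = config$personal_intercept),
            class = "mebn_sim")
}

#' @export
print.mebn_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Simulated study: %d subjects x %d weeks, %d predictors, %d response(s)\n",
              cfg$s, length(cfg$weeks), length(cfg$predictors),
              length(cfg$responses)))
  invisible(x)
}

#' Serialize / restore a truth record
#'
#' Exact round trip (full numeric precision) of the generation-time latents.
#'
#' @param truth a truth record from [simulate_study()].
#' @param file path to a JSON file.
#' @return `write_truth_json` returns `file` invisibly; `read_truth_json`
#'   the truth record.
#' @export
write_truth_json <- function(truth, file) {
  writeLines(jsonlite::serializeJSON(truth, digits = 17), file)
  invisible(file)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(file) {
  jsonlite::unserializeJSON(paste(readLines(file), collapse = "\n"))
}

#' Canonical study fixture mirroring a dietary-intervention design
#'
#' 106 subjects over weeks 0/4/8/12; 22 predictors (20 continuous nutrient
#' intakes plus standardized binary sex and cholesterol-medication columns);
#' five blood concentrations: four Gamma-family (total, HDL and LDL
#' cholesterol, glucose) and one Normal-family (insulin), giving 110
#' candidate effects. Effect magnitudes echo the scale of reported
#' inter-subject variation (the largest personal-effect sd near 4.3, on
#' insulin), with intercepts near typical concentration levels so the
#' identity-link Gamma means stay positive.
#'
#' @param seed integer seed.
#' @return the simulated study table (data frame, 424 x 29) with the truth
#'   record as attribute `truth` and the matching spec as attribute `spec`.
#' @export
make_sysdimet_like <- function(seed = 1) {
  nutrients <- c("energy", "protein", "fat", "safa", "mufa", "pufa",
                 "linoleic_acid", "epa", "dha", "carbohydrate", "sucrose",
                 "fibre", "lignin", "cellulose", "alcohol", "vitamin_c",
                 "vitamin_d", "folic_acid", "alpha_lipoic_acid",
                 "cholesterol_intake")
  predictors <- c(nutrients, "sex", "chol_medication")
  responses <- c("total_chol", "hdl_chol", "ldl_chol", "glucose", "insulin")
  p <- length(predictors)

  B <- matrix(0, 5, p + 1, dimnames = list(responses,
                                           c("(Intercept)", predictors)))
  B[, 1] <- c(5.5, 1.6, 3.4, 6.0, 22)
  B["total_chol", c("safa", "fibre", "chol_medication")] <- c(0.25, -0.15, -1.0)
  B["hdl_chol", c("mufa", "alcohol", "sex")] <- c(0.08, 0.05, 0.2)
  B["ldl_chol", c("safa", "fibre", "chol_medication", "sex")] <-
    c(0.3, -0.2, -0.8, -0.4)
  B["glucose", c("sucrose", "fibre", "sex")] <- c(0.2, -0.1, -0.3)
  B["insulin", c("energy", "sucrose", "safa", "sex", "chol_medication")] <-
    c(1.3, 0.8, 0.8, -3.9, 1.5)

  q <- p + 1  # personal intercept + all predictors
  SB <- matrix(0.05, 5, q)
  SB[, 1] <- c(0.4, 0.2, 0.3, 0.4, 2.0)  # personal baselines
  cx <- function(nm) match(nm, predictors) + 1L
  SB[5, cx(c("energy", "pufa", "epa", "mufa", "safa", "sucrose"))] <-
    c(4.29, 1.35, 1.11, 0.97, 0.83, 0.85)
  SB[5, cx(c("sex", "chol_medication"))] <- c(3.93, 1.46)
  SB[1, cx(c("sex", "chol_medication", "energy"))] <- c(0.59, 0.48, 0.36)
  SB[3, cx(c("sex", "chol_medication", "energy"))] <- c(0.53, 0.36, 0.23)
  SB[4, cx(c("sex", "energy", "sucrose"))] <- c(0.30, 0.23, 0.12)
  SB[2, cx(c("sex", "chol_medication", "energy"))] <- c(0.24, 0.18, 0.17)

  cfg <- sim_config(
    s = 106, weeks = c(0, 4, 8, 12), predictors = predictors,
    binary = c("sex", "chol_medication"), responses = responses,
    beta = B, sigma_b = SB, rho = c(0.3, 0.3, 0.3, 0.25, 0.35),
    families = c("gamma", "gamma", "gamma", "gamma", "normal"),
    dispersion = c(80, 120, 80, 150, 4))
  sim <- simulate_study(cfg, seed = seed)
  structure(sim$data, truth = sim$truth, spec = attr(sim, "spec"))
}

#' Parameter-recovery report against a known truth
#'
#' Compares a fitted network (or single local) with the generating truth
#' record: bias, RMSE and 90%-interval coverage for the general coefficients,
#' the personal-effect sds, the effect correlations, and the AR(1)
#' coefficient.
#'
#' @param truth truth record from [simulate_study()].
#' @param fit the [mebn()] or [mebn_local()] fitted on the simulated table.
#' @return data frame: response, class, bias, rmse, coverage90, n.
#' @export
recovery_report <- function(truth, fit) {
  locals <- if (inherits(fit, "mebn")) fit$locals else
    setNames(list(fit), fit$response)
  cfg <- truth$config
  rows <- list()
  for (r in names(locals)) {
    loc <- locals[[r]]
    i <- match(r, cfg$responses)
    if (is.na(i)) stop("response '", r, "' absent from the truth record")
    if (length(loc$predictors) != ncol(cfg$beta))
      stop("dimension mismatch between truth and fit for '", r, "'")
    cl <- function(draws, true) {
      est <- colMeans(draws)
      lo <- apply(draws, 2, quantile, 0.05)
      hi <- apply(draws, 2, quantile, 0.95)
      c(bias = mean(est - true), rmse = sqrt(mean((est - true)^2)),
        coverage90 = mean(true >= lo & true <= hi), n = length(true))
    }
    out <- list(beta = cl(loc$draws$beta, cfg$beta[i, ]))
    if (length(loc$personal) == ncol(cfg$sigma_b))
      out$sigma_b <- cl(loc$draws$sigma_b, cfg$sigma_b[i, ])
    if (!is.null(loc$draws$u) && nrow(cfg$C[[i]]) == length(loc$personal)) {
      Q <- length(loc$personal)
      lowidx <- which(lower.tri(diag(Q)))
      cd <- t(vapply(seq_len(nrow(loc$draws$u)), function(d) {
        L <- .chol_from_u(loc$draws$u[d, ], Q); (L %*% t(L))[lowidx]
      }, numeric(length(lowidx))))
      out$C <- cl(cd, cfg$C[[i]][lowidx])
    }
    if (loc$ar1)
      out$rho <- cl(matrix(loc$draws$rho, ncol = 1), cfg$rho[i])
    for (nm in names(out))
      rows[[length(rows) + 1L]] <- data.frame(
        response = r, class = nm, t(out[[nm]]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
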