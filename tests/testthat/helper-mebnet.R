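# Shared fixtures. MCMC fits are memoized so several test files can reuse the
# same small fitted network without refitting.

quick_sampler <- list(chains = 2, adapt = 300, burn = 300, iter = 400)

.fixtures <- new.env(parent = emptyenv())

tiny_config <- function() {
  sim_config(s = 30, p = 4, v = 2, personal = c("x01", "x02"),
             beta = rbind(c(10, 1, -0.8, 0.4, 0), c(8, 0.5, 0, 0, 0.7)),
             sigma_b = rbind(c(0.5, 0.6, 0.4), c(0.3, 0.4, 0.2)),
             C = matrix(c(1, 0.4, 0.1, 0.4, 1, 0.2, 0.1, 0.2, 1), 3),
             rho = 0.3, families = c("gamma", "normal"),
             dispersion = c(60, 0.8))
}

tiny_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_study(tiny_config(), seed = 7)
  .fixtures$sim
}

tiny_fit <- function() {
  if (is.null(.fixtures$fit)) {
    sim <- tiny_sim()
    .fixtures$fit <- do.call(mebn, c(list(sim$data, attr(sim, "spec"), seed = 3),
                                     quick_sampler))
  }
  .fixtures$fit
}

# A point-mass "posterior" standing in for a known generating process:
# subjects' deviations are passed through z with unit scales so b == z.
local_from_truth <- function(truth, response, spec) {
  i <- match(response, truth$config$responses)
  b <- truth$b[[response]]
  mebn_local_from_params(
    response = response,
    predictors = truth$config$predictors,
    personal = truth$zcols,
    subjects = truth$subjects,
    family = truth$config$families[[response]],
    beta = truth$config$beta[i, ],
    sigma_b = rep(1, ncol(b)), C = diag(ncol(b)), z = b,
    rho = truth$config$rho[i],
    dispersion = truth$config$dispersion[[response]],
    grid = truth$config$weeks)
}

net_from_truth <- function(sim) {
  spec <- attr(sim, "spec")
  locals <- lapply(spec$responses, function(r)
    local_from_truth(sim$truth, r, spec))
  net <- mebn_assemble(locals, spec, data = sim$data)
  net
}
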