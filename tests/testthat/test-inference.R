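test_that("personal-effect composition b = T L z does the right algebra", {
  expect_equal(compose_personal_effect(c(2, 1), diag(2), c(0, 0)), c(0, 0))
  expect_equal(compose_personal_effect(c(3, 2), diag(2), c(1, -1)), c(3, -2))
  L <- rbind(c(1, 0), c(0.6, 0.8))
  expect_equal(compose_personal_effect(c(2, 1), L, c(1, 1)), c(2, 1.4))
  expect_error(compose_personal_effect(c(1, 1), L, c(1, 1, 1)))
})

test_that("effect correlations reconstruct C = LL' with exact unit diagonal", {
  C <- matrix(c(1, 0.6, 0.6, 1), 2,
              dimnames = NULL)
  loc <- mebn_local_from_params("y", c("x1", "x2"), c("x1", "x2"),
                                subjects = "S1", beta = c(0, 0, 0),
                                sigma_b = c(1, 1), C = C)
  ec <- effect_correlations(loc)
  expect_equal(unname(ec$mean[1, 2]), 0.6, tolerance = 1e-10)
  expect_equal(unname(diag(ec$mean)), c(1, 1), tolerance = 1e-12)
  # single personal column degenerates to the 1x1 matrix [1]
  loc1 <- mebn_local_from_params("y", c("x1"), "x1", subjects = "S1",
                                 beta = c(0, 0), sigma_b = 1)
  expect_equal(unname(effect_correlations(loc1)$mean), matrix(1, 1, 1))
})

test_that("network assembly enforces completeness and shared provenance", {
  spec <- mebn_spec(c("a", "b"), "x", families = "normal")
  la <- mebn_local_from_params("a", "x", "x", "S1", beta = c(0, 0), sigma_b = 1)
  lb <- mebn_local_from_params("b", "x", "x", "S1", beta = c(0, 0), sigma_b = 1)
  net <- mebn_assemble(list(la, lb), spec)
  expect_s3_class(net, "mebn")
  expect_error(mebn_assemble(list(la), spec), "missing.*b")
  lc <- mebn_local_from_params("c", "x", "x", "S1", beta = c(0, 0), sigma_b = 1)
  expect_error(mebn_assemble(list(la, lb, lc), spec), "not in spec")
  la$data_hash <- "aaa"; lb$data_hash <- "bbb"
  expect_error(mebn_assemble(list(la, lb), spec), "hash")
})

test_that("fitted local posteriors satisfy the covariance-geometry invariants", {
  fit <- tiny_fit()
  loc <- fit$locals$y1
  Q <- length(loc$personal)
  idx <- seq(1, nrow(loc$draws$u), length.out = 50)
  for (d in round(idx)) {
    L <- mebnet:::.chol_from_u(loc$draws$u[d, ], Q)
    C <- L %*% t(L)
    expect_lt(max(abs(diag(C) - 1)), 1e-12)
    expect_true(all(abs(C[lower.tri(C)]) <= 1 + 1e-12))
    Tm <- diag(loc$draws$sigma_b[d, ], nrow = Q)
    Sigma <- Tm %*% C %*% Tm
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
  expect_true(all(loc$draws$sigma_b >= 0))
  expect_true(all(abs(loc$draws$rho) < 1))
  expect_true(all(loc$draws$dispersion > 0))
})

test_that("diagnostics are reported and summaries ignore chain order", {
  fit <- tiny_fit()
  loc <- fit$locals$y2
  expect_true(all(is.finite(loc$diagnostics$rhat)))
  expect_true(all(loc$diagnostics$ess > 0))
  expect_equal(loc$diagnostics$n_chains, 2)
  # swapping the chain blocks leaves pooled summaries untouched
  perm <- order(-loc$draws$chain, seq_along(loc$draws$chain))
  expect_equal(colMeans(loc$draws$beta[perm, ]), colMeans(loc$draws$beta))
  expect_equal(apply(loc$draws$beta[perm, ], 2, quantile, 0.05),
               apply(loc$draws$beta, 2, quantile, 0.05))
})

test_that("baseline week can be demoted to AR-input-only without breaking the fit", {
  cfg <- sim_config(s = 20, p = 2, personal = "x01",
                    beta = c(5, 1, -0.5), sigma_b = 0.3, rho = 0.4,
                    families = "normal", dispersion = 0.5)
  sim <- simulate_study(cfg, seed = 3)
  loc <- mebn_local(sim$data, attr(sim, "spec"), "y1", chains = 1,
                    adapt = 200, burn = 200, iter = 200, seed = 2,
                    baseline_outcome = FALSE)
  expect_s3_class(loc, "mebn_local")
  expect_gt(cor(coef(loc), c(5, 1, -0.5)), 0.99)
})

test_that("strong general effects are recovered with high correlation to truth", {
  beta <- c(8, 1.5, -1.2, 1.0, -1.5, 1.2, -1.0)
  cfg <- sim_config(s = 80, p = 6, personal = "x01",
                    beta = beta, sigma_b = c(0.5, 0.5), rho = 0.3,
                    families = "normal", dispersion = 0.7)
  sim <- simulate_study(cfg, seed = 13)
  loc <- do.call(mebn_local,
                 c(list(sim$data, attr(sim, "spec"), "y1", seed = 5),
                   quick_sampler))
  est <- coef(loc)
  expect_gt(cor(est, beta), 0.9)
  # personal effects for a known subject line up with beta + b summaries
  pe <- personal_effects(loc, "S001")
  expect_equal(pe$effect_mean - pe$b_mean,
               unname(est[pe$predictor]), tolerance = 1e-10)
  expect_error(personal_effects(loc, "nobody"), "unknown subject")
})
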