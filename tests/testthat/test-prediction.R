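test_that("AR(1) expectation is the residual-carryover formula", {
  expect_equal(ar1_expected(2, 2, 3, 0.5), 2.5)
  expect_equal(ar1_expected(2, 2, 2, 0.7), 2)     # zero residual
  expect_equal(ar1_expected(4, 1, 3, 0), 4)       # no serial correlation
  # linear in y_prev with slope exactly rho
  rho <- 0.37
  ys <- c(-2, 0, 1, 5)
  out <- ar1_expected(1, 0.5, ys, rho)
  expect_equal(diff(out) / diff(ys), rep(rho, 3))
  expect_error(ar1_expected(1, 1, 1, 1.2), "rho")
})

test_that("NRMSE normalizes RMSE by the mean level", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(3, 3, 3), c(2, 2, 2)), 0.5)
  expect_equal(network_nrmse(c(0.1, 0.3)), 0.2)
  # invariant to common positive rescaling
  set.seed(1)
  p <- runif(10, 1, 2); o <- runif(10, 1, 2)
  expect_equal(nrmse(7 * p, 7 * o, 7 * mean(o)), nrmse(p, o))
  expect_error(nrmse(1, numeric(0)))
  expect_error(nrmse(c(1, 2), c(1, 2), ybar = 0), "nonzero")
  expect_error(nrmse(numeric(0), numeric(0)), "empty")
})

make_pred_net <- function(family = "normal", dispersion = 1e-8, rho = 0.4,
                          b = NULL, subjects = c("S1", "S2")) {
  spec <- mebn_spec("y", c("x1", "x2"), personal = "x1", families = family)
  z <- if (is.null(b)) matrix(0, length(subjects), 2) else b
  loc <- mebn_local_from_params("y", c("x1", "x2"), c("(Intercept)", "x1"),
                                subjects = subjects, family = family,
                                beta = c(5, 1, -0.5), sigma_b = c(1, 1),
                                C = diag(2), z = z, rho = rho,
                                dispersion = dispersion)
  mebn_assemble(list(loc), spec)
}

pred_data <- function() {
  data.frame(subject_id = rep(c("S1", "S2"), each = 2),
             week = rep(c(0, 4), 2),
             x1 = c(0.5, -0.5, 1, -1), x2 = c(0, 1, -1, 0),
             y = c(6, NA, 4, NA))
}

test_that("ancestral sampling is seed-reproducible and respects the family support", {
  net <- make_pred_net()
  nd <- pred_data()
  p1 <- predict(net, nd, n_draws = 50, seed = 42)
  p2 <- predict(net, nd, n_draws = 50, seed = 42)
  expect_identical(p1$mean, p2$mean)
  expect_identical(attr(p1, "draws"), attr(p2, "draws"))
  netg <- make_pred_net(family = "gamma", dispersion = 30)
  pg <- predict(netg, nd, n_draws = 100, seed = 1)
  expect_true(all(attr(pg, "draws")$y > 0))
})

test_that("with vanishing noise the predictive mean equals the linear predictor", {
  net <- make_pred_net(rho = 0.4)
  nd <- pred_data()
  pred <- predict(net, nd, n_draws = 20, seed = 3)
  # week 0: mu = 5 + x1 - 0.5 x2 ; week 4 adds rho * (y_obs_prev - mu_prev)
  mu0_s1 <- 5 + 0.5; mu0_s2 <- 5 + 1 - 0.5 * (-1)
  expect_equal(pred$mean[pred$subject_id == "S1" & pred$week == 0], mu0_s1,
               tolerance = 1e-6)
  mu4_s1 <- (5 - 0.5 - 0.5 * 1) + 0.4 * (6 - mu0_s1)
  expect_equal(pred$mean[pred$subject_id == "S1" & pred$week == 4], mu4_s1,
               tolerance = 1e-6)
  expect_true(all(pred$ar_used[pred$week == 4]))
  expect_false(any(pred$ar_used[pred$week == 0]))
})

test_that("unknown subjects fall back to population-level predictions", {
  b <- rbind(c(2, 1), c(-1, 0.5))
  net <- make_pred_net(b = b)
  nd <- pred_data()
  nd$subject_id <- rep(c("S1", "S9"), each = 2)  # S9 unseen
  pred <- predict(net, nd, n_draws = 10, seed = 1, use_ar = FALSE)
  expect_true(all(pred$personal_used[pred$subject_id == "S1"]))
  expect_false(any(pred$personal_used[pred$subject_id == "S9"]))
  # S9 week 0 prediction is the b = 0 value
  expect_equal(pred$mean[pred$subject_id == "S9" & pred$week == 0],
               5 + 1 - 0.5 * (-1), tolerance = 1e-6)
  # S1 week 0 includes its personal intercept and slope
  expect_equal(pred$mean[pred$subject_id == "S1" & pred$week == 0],
               5 + 2 + (1 + 1) * 0.5, tolerance = 1e-6)
})

test_that("posterior predictive checks pass on the generator and flag misspecification", {
  fit <- tiny_fit()
  pp <- ppc(fit, n_draws = 150, seed = 2)
  means <- pp[pp$stat == "mean", ]
  expect_true(all(means$inside))
  expect_error(ppc(fit, data = fit$data[0, ]), "empty")

  # normal local forced onto strongly right-skewed gamma data
  cfg <- sim_config(s = 150, p = 1, beta = c(2, 0), sigma_b = 0, rho = 0,
                    families = "gamma", dispersion = 1.5)
  sim <- simulate_study(cfg, seed = 8)
  spec_n <- mebn_spec("y1", "x01", families = "normal")
  loc <- mebn_local_from_params("y1", "x01", "(Intercept)",
                                subjects = unique(sim$data$subject_id),
                                family = "normal",
                                beta = c(mean(sim$data$y1), 0), sigma_b = 0,
                                dispersion = sd(sim$data$y1))
  net <- mebn_assemble(list(loc), spec_n, data = sim$data)
  pp2 <- ppc(net, n_draws = 200, seed = 5)
  expect_false(pp2$inside[pp2$stat == "skewness"])
})

test_that("in-sample metric report aggregates per-response NRMSE into the network mean", {
  fit <- tiny_fit()
  mr <- metric_report(fit, n_draws = 100, seed = 4)
  expect_equal(nrow(mr$per_response), 2)
  expect_true(all(mr$per_response$nrmse > 0))
  expect_equal(mr$network, mean(mr$per_response$nrmse))
})
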