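test_that("degenerate generator collapses to the deterministic linear predictor", {
  cfg <- sim_config(s = 12, p = 3, beta = c(5, 1, -0.5, 0.25), sigma_b = 0,
                    rho = 0, families = "normal", dispersion = 1e-9)
  sim <- simulate_study(cfg, seed = 2)
  X <- cbind(1, as.matrix(sim$data[c("x01", "x02", "x03")]))
  expect_equal(sim$data$y1, as.numeric(X %*% c(5, 1, -0.5, 0.25)),
               tolerance = 1e-7)
})

test_that("gamma-family simulation stays strictly positive and rejects bad configs", {
  cfg <- sim_config(s = 200, p = 3, beta = c(6, 0.5, -0.5, 0.2),
                    sigma_b = 0.3, rho = 0.4, families = "gamma",
                    dispersion = 30)
  sim <- simulate_study(cfg, seed = 5)
  expect_true(all(sim$data$y1 > 0))
  bad <- sim_config(s = 20, p = 2, beta = c(0.1, 3, 3), sigma_b = 0,
                    rho = 0, families = "gamma")
  expect_error(simulate_study(bad, seed = 1), "intercept")
})

test_that("residual lag-1 autocorrelation matches the AR(1) coefficient", {
  rho <- 0.5
  cfg <- sim_config(s = 1500, p = 2, beta = c(3, 0.5, -0.3), sigma_b = 0,
                    rho = rho, families = "normal", dispersion = 1)
  sim <- simulate_study(cfg, seed = 9)
  res <- sim$data$y1 - sim$truth$mu$y1
  nk <- length(cfg$weeks)
  m <- matrix(res, nrow = nk)
  r_pairs <- cor(as.vector(m[-nk, ]), as.vector(m[-1, ]))
  n_pairs <- (nk - 1) * cfg$s
  se <- (1 - rho^2) / sqrt(n_pairs)
  expect_lt(abs(r_pairs - rho), 3 * se)
})

test_that("personal-effect sample covariance converges to T C T'", {
  Ct <- matrix(c(1, 0.5, 0.5, 1), 2)
  make <- function(s, seed) {
    cfg <- sim_config(s = s, p = 2, personal = c("x01", "x02"),
                      personal_intercept = FALSE,
                      beta = c(0, 0, 0), sigma_b = c(1.5, 0.8), C = Ct,
                      rho = 0, families = "normal", dispersion = 1)
    sim <- simulate_study(cfg, seed = seed)
    target <- diag(c(1.5, 0.8)) %*% Ct %*% diag(c(1.5, 0.8))
    sqrt(sum((cov(sim$truth$b$y1) - target)^2))
  }
  d_small <- make(100, 21)
  d_large <- make(2000, 22)
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.15)
})

test_that("AR(1) residual sequence is stationary across time points", {
  cfg <- sim_config(s = 4000, p = 1, beta = c(0, 0), sigma_b = 0, rho = 0.6,
                    families = "normal", dispersion = 1)
  sim <- simulate_study(cfg, seed = 31)
  res <- matrix(sim$data$y1 - sim$truth$mu$y1, nrow = length(cfg$weeks))
  v <- apply(res, 1, var)
  target <- 1 / (1 - 0.6^2)
  se <- target * sqrt(2 / (cfg$s - 1))
  expect_true(all(abs(v - target) < 4 * se))
})

test_that("the canonical study fixture has the documented shape and determinism", {
  tab <- make_sysdimet_like(seed = 4)
  expect_equal(dim(tab), c(106 * 4, 2 + 22 + 5))
  expect_equal(n_edges(attr(tab, "spec")), 110)
  expect_true(all(tab$glucose > 0))
  # binary columns standardized: exactly two distinct values, mean ~ 0
  expect_equal(length(unique(tab$sex)), 2)
  expect_equal(mean(tab$sex), 0, tolerance = 1e-12)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_study_table(tab, f1)
  write_study_table(make_sysdimet_like(seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("truth records round-trip through serialization exactly", {
  sim <- simulate_study(sim_config(s = 6, p = 2), seed = 3)
  f <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, f)
  back <- read_truth_json(f)
  expect_identical(back$beta, sim$truth$beta)
  expect_identical(back$b$y1, sim$truth$b$y1)
  expect_identical(back$mu$y1, sim$truth$mu$y1)
  unlink(f)
})
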