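# A deterministic network from known parameters: 2 responses, 3 predictors,
# personal slopes on x1/x2 (no personal intercept so columns are pure effects).
toy_net <- function(sigma_b = c(1, 0.5), b1 = NULL, b2 = NULL, S = 8,
                    beta1 = c(5, 1, -0.5, 0.2), beta2 = c(3, 0.4, 0, -0.1)) {
  spec <- mebn_spec(c("r1", "r2"), c("x1", "x2", "x3"),
                    personal = c("x1", "x2"), families = "normal",
                    personal_intercept = FALSE)
  subj <- sprintf("S%02d", seq_len(S))
  mk <- function(resp, beta, b) {
    if (is.null(b)) b <- matrix(0, S, 2)
    mebn_local_from_params(resp, c("x1", "x2", "x3"), c("x1", "x2"),
                           subjects = subj, beta = beta,
                           sigma_b = sigma_b, z = b, dispersion = 1)
  }
  mebn_assemble(list(mk("r1", beta1, b1), mk("r2", beta2, b2)), spec)
}

test_that("effect table has v x p_z columns and collapses when sigma_b = 0", {
  net0 <- toy_net(sigma_b = c(0, 0))
  et <- effect_table(net0)
  expect_equal(dim(et$mean), c(8, 2 * 2))
  expect_true(all(apply(et$mean, 2, var) == 0))  # identical rows
  et_sub <- effect_table(net0, predictors = "x1")
  expect_equal(ncol(et_sub$mean), 2)
  expect_equal(colnames(et$mean),
               c("r1:x1", "r1:x2", "r2:x1", "r2:x2"))
})

test_that("planted blob structure is found by the elbow scan and k-means exactly", {
  set.seed(99)
  centers <- matrix(rnorm(4 * 6, sd = 5), 4, 6)
  lab <- rep(1:4, times = c(30, 25, 25, 26))
  m <- centers[lab, ] + matrix(rnorm(106 * 6, sd = 0.3), 106, 6)
  rownames(m) <- sprintf("S%03d", 1:106)
  el <- elbow_scan(m, k_range = 1:8, seed = 1)
  expect_equal(attr(el, "suggested"), 4)
  expect_true(all(diff(el$wss) <= 1e-8))
  cl <- kmeans_cluster(m, 4, seed = 1)
  expect_equal(sort(cl$sizes), c(25, 25, 26, 30))
  tab <- table(lab, cl$labels)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))  # pure clusters
  expect_equal(sum(cl$percent), 100)
  # clustering quality is invariant to column permutation
  cl_perm <- kmeans_cluster(m[, c(3, 1, 6, 2, 5, 4)], 4, seed = 1)
  expect_equal(cl_perm$wss, cl$wss, tolerance = 1e-8)
})

test_that("k-means edge cases: one cluster, singleton clusters", {
  m <- matrix(rnorm(40), 10, 4, dimnames = list(letters[1:10], NULL))
  c1 <- kmeans_cluster(m, 1, seed = 2)
  expect_equal(unname(c1$centers[1, ]), unname(colMeans(m)))
  cn <- kmeans_cluster(m, 10, seed = 2)
  expect_equal(cn$wss, 0, tolerance = 1e-12)
  expect_error(kmeans_cluster(m, 11), "exceeds")
})

test_that("variation ranking orders by sigma_b, filters at the threshold, keeps min <= max", {
  set.seed(5)
  b1 <- cbind(rnorm(8), rep(0, 8))        # x1 carries the planted variation
  net <- toy_net(sigma_b = c(2, 0.05), b1 = b1)
  rv <- rank_varying_effects(net, threshold = 0)
  expect_equal(rv$predictor[1], "x1")
  expect_equal(rv$response[1], "r1")
  expect_true(all(diff(rv$sigma_b) <= 0))
  expect_true(all(rv$min_effect <= rv$max_effect))
  rv_f <- rank_varying_effects(net, threshold = 0.10)
  expect_true(all(rv_f$sigma_b > 0.10))
  expect_lt(nrow(rv_f), nrow(rv))
})

test_that("effect-graph export keeps the top edges with correct signs", {
  net <- toy_net()
  g <- export_effect_graph(net, top_n = 3)
  expect_equal(nrow(g), 3)
  expect_equal(g$weight, abs(g$effect))
  expect_equal(g$sign, sign(g$effect))
  expect_equal(g$predictor[1], "x1")  # |1| is the largest general effect
  # all-zero generals give an empty graph at any positive threshold
  net0 <- toy_net(beta1 = rep(0, 4), beta2 = rep(0, 4))
  g0 <- export_effect_graph(net0, threshold = 0.01)
  expect_equal(nrow(g0), 0)
  # subject mode swaps in beta + b for the personal columns
  b1 <- rbind(matrix(0, 7, 2), c(3, 0))
  netp <- toy_net(b1 = b1)
  gs <- export_effect_graph(netp, mode = "subject", subject = "S08", top_n = 2)
  expect_equal(gs$effect[gs$predictor == "x1" & gs$response == "r1"], 1 + 3)
  f <- tempfile(fileext = ".graphml")
  export_effect_graph(net, top_n = 4, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})
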