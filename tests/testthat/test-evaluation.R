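test_that("fold plans partition subjects with balanced sizes per split", {
  subj <- sprintf("S%03d", 1:106)
  plan <- cv_folds(subj, n_folds = 10, seed = 1)
  for (sp in 1:3) {
    part <- plan[plan$split == sp, ]
    expect_setequal(part$subject_id, subj)          # exactly one fold each
    sizes <- as.integer(table(part$fold))
    expect_true(all(sizes %in% c(10, 11)))
    expect_equal(sort(sizes), c(rep(10, 4), rep(11, 6)))
  }
  expect_false(0 %in% plan$heldout_week)
  expect_setequal(unique(plan$heldout_week), c(4, 8, 12))
  # each (subject, post-baseline week) held out exactly once across the plan
  cells <- table(plan$subject_id, plan$heldout_week)
  expect_true(all(cells == 1))
})

test_that("fold plans are deterministic under a seed and handle edge sizes", {
  subj <- letters[1:10]
  p1 <- cv_folds(subj, n_folds = 10, seed = 9)
  p2 <- cv_folds(subj, n_folds = 10, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(table(p1$subject_id[p1$split == 1], p1$fold[p1$split == 1]) <= 1))
  expect_equal(as.integer(table(p1$fold[p1$split == 1])), rep(1, 10))
  expect_error(cv_folds(letters[1:5], n_folds = 10), "fewer subjects")
  expect_error(cv_folds(subj, weeks = c(0, 4, 8, 12), n_splits = 2),
               "post-baseline")
})

test_that("direction classification applies the strict-increase rule with decrease ties", {
  expect_equal(predict_direction(5.2, 5.0), "increase")
  expect_equal(predict_direction(4.8, 5.0), "decrease")
  expect_equal(predict_direction(5.0, 5.0), "decrease")
  expect_error(predict_direction(5, NA), "missing")
  rec <- data.frame(response = rep(c("a", "b"), each = 3),
                    predicted_direction = c("increase", "decrease", "increase",
                                            "decrease", "decrease", "increase"),
                    true_direction = c("increase", "increase", "increase",
                                       "decrease", "increase", "decrease"))
  acc <- direction_accuracy(rec)
  expect_equal(acc$accuracy[acc$group == "overall"], 0.5)
  expect_equal(acc$accuracy[acc$group == "a"], 2 / 3)
  expect_error(direction_accuracy(rec[0, ]), "empty")
  # invariance under a joint monotone transform of values
  set.seed(4)
  pv <- runif(50); lo <- runif(50)
  expect_identical(predict_direction(pv, lo),
                   predict_direction(exp(pv), exp(lo)))
})

test_that("the CV harness refits without leakage and logs every fold", {
  cfg <- sim_config(s = 12, p = 2, personal = "x01",
                    beta = c(6, 1, -0.6), sigma_b = c(0.4, 0.5), rho = 0.35,
                    families = "normal", dispersion = 0.5)
  sim <- simulate_study(cfg, seed = 17)
  plan <- cv_folds(unique(sim$data$subject_id), n_folds = 2, seed = 3)
  cvr <- run_cv(sim$data, attr(sim, "spec"), plan, chains = 1, adapt = 200,
                burn = 200, iter = 250, n_draws = 60, seed = 19)
  expect_length(cvr$fold_log, 3 * 2)
  expect_length(cvr$failures, 0)
  held_all <- list()
  for (fl in cvr$fold_log) {
    expect_length(intersect(fl$train_rows, fl$test_rows), 0)
    expect_setequal(c(fl$train_rows, fl$test_rows), seq_len(nrow(sim$data)))
    # held-out response cells absent from the training rows
    held <- sim$data[fl$test_rows, c("subject_id", "week")]
    train <- sim$data[fl$train_rows, c("subject_id", "week")]
    expect_equal(nrow(merge(held, train)), 0)
    held_all[[length(held_all) + 1L]] <- held
  }
  held_all <- do.call(rbind, held_all)
  # across the whole plan each post-baseline cell is held out exactly once
  expect_true(all(table(held_all$subject_id, held_all$week) == 1))
  expect_false(0 %in% held_all$week)
  m <- cvr$metrics
  expect_true(all(is.finite(m$cv_nrmse)))
  expect_true(all(m$cv_acc >= 0 & m$cv_acc <= 1))
  # generalization gap: out-of-sample error is not better than in-sample
  # beyond Monte Carlo noise
  expect_gt(m$cv_nrmse[m$response == "network"],
            m$in_nrmse[m$response == "network"] - 0.05)
})

test_that("baseline adapters share the fold contract; a constant baseline has closed-form accuracy", {
  sim <- tiny_sim()
  plan <- cv_folds(unique(sim$data$subject_id), n_folds = 3, seed = 5)
  rec <- run_cv_baseline(sim$data, plan, "y1", baseline_always_decrease)
  expect_true(all(rec$predicted_direction == "decrease"))
  acc <- direction_accuracy(rec)
  expect_equal(acc$accuracy[acc$group == "overall"],
               mean(rec$true_direction == "decrease"))
  # every post-baseline cell appears exactly once
  expect_true(all(table(rec$subject_id, rec$week) == 1))
  expect_message(out <- run_cv_baseline(sim$data, plan, "y1", NULL), "skipped")
  expect_null(out)
})
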