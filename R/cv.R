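#' Fold plan for subject-level time-series cross-validation
#'
#' Splits the repeated-measurement series into `n_splits` parts, one per
#' post-baseline week: split \eqn{i} holds out week `weeks[i + 1]` for one
#' fold of subjects at a time. Within every split the subjects are
#' partitioned into `n_folds` folds of near-equal size (difference at most
#' one), so each (subject, post-baseline week) cell is held out exactly once
#' across the plan. The baseline week is never held out; it serves only as an
#' AR(1) input.
#'
#' @param subjects subject identifiers.
#' @param weeks the shared ordered week grid; default `c(0, 4, 8, 12)`.
#' @param n_folds folds per split (default 10).
#' @param n_splits number of splits; must equal `length(weeks) - 1`.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return class `mebn_folds`: data frame (split, fold, subject_id,
#'   heldout_week) with the seed and grid as attributes.
#' @export
cv_folds <- function(subjects, weeks = c(0, 4, 8, 12), n_folds = 10,
                     n_splits = length(weeks) - 1, seed = 1) {
  subjects <- as.character(unique(subjects))
  if (length(subjects) < n_folds)
    stop("fewer subjects (", length(subjects), ") than folds (", n_folds, ")")
  if (n_splits != length(weeks) - 1)
    stop("n_splits must equal the number of post-baseline weeks")
  weeks <- sort(weeks)
  set.seed(as.integer(seed))
  plans <- lapply(seq_len(n_splits), function(sp) {
    shuffled <- sample(subjects)
    fold <- rep_len(seq_len(n_folds), length(subjects))
    data.frame(split = sp, fold = fold, subject_id = shuffled,
               heldout_week = weeks[sp + 1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, plans)
  rownames(out) <- NULL
  structure(out, seed = seed, n_folds = n_folds, n_splits = n_splits,
            weeks = weeks, class = c("mebn_folds", "data.frame"))
}

#' Direction-of-change classification
#'
#' `predict_direction` classifies a predicted concentration against the last
#' observed value: `"increase"` iff the predictive mean strictly exceeds it,
#' otherwise `"decrease"` (exact ties, a measure-zero event for continuous
#' predictions, count as `"decrease"`). `direction_accuracy` is the
#' proportion of records whose predicted direction matches the true one.
#'
#' @param predicted predictive means.
#' @param last_observed previous observed values.
#' @return character vector of `"increase"`/`"decrease"`.
#' @export
predict_direction <- function(predicted, last_observed) {
  if (any(is.na(last_observed))) stop("missing last observation")
  ifelse(predicted > last_observed, "increase", "decrease")
}

#' @rdname predict_direction
#' @param records data frame with columns `response`, `predicted_direction`,
#'   `true_direction`.
#' @param by grouping column (default `"response"`).
#' @return for `direction_accuracy`, a data frame of per-group accuracies
#'   plus an `overall` row.
#' @export
direction_accuracy <- function(records, by = "response") {
  if (!nrow(records)) stop("empty records")
  hit <- records$predicted_direction == records$true_direction
  acc <- tapply(hit, records[[by]], mean)
  out <- data.frame(group = c(names(acc), "overall"),
                    accuracy = c(as.numeric(acc), mean(hit)),
                    n = c(as.integer(table(records[[by]])[names(acc)]),
                          nrow(records)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Direction records for a set of predicted cells. True direction compares the
# observed value with the previous week's observed value; exactly unchanged
# observations count as "decrease", mirroring the prediction tie rule.
.direction_records <- function(pred, data, responses) {
  data <- data[order(data$subject_id, data$week), ]
  key <- paste(data$subject_id, data$week)
  grid <- sort(unique(data$week))
  rows <- list()
  for (r in responses) {
    p <- pred[pred$response == r, ]
    tix <- match(p$week, grid)
    prev_key <- paste(p$subject_id, grid[ifelse(tix > 1, tix - 1, 1)])
    last_obs <- data[[r]][match(prev_key, key)]
    yobs <- data[[r]][match(paste(p$subject_id, p$week), key)]
    ok <- tix > 1 & !is.na(last_obs) & !is.na(yobs)
    if (!any(ok)) next
    rows[[r]] <- data.frame(
      subject_id = p$subject_id[ok], week = p$week[ok], response = r,
      predicted_value = p$mean[ok], last_observed = last_obs[ok],
      predicted_direction = predict_direction(p$mean[ok], last_obs[ok]),
      true_direction = ifelse(yobs[ok] > last_obs[ok], "increase", "decrease"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the cross-validation harness
#'
#' For every (split, fold) of the plan: refits the network on the table
#' without the held-out (subject, week) rows, predicts the held-out cells
#' using the previous week's observation as the AR(1) input, and accumulates
#' NRMSE and direction-of-change records. In-sample metrics from a fit on the
#' full table are reported for contrast. A local fit failure marks the fold
#' failed and the run continues.
#'
#' @param data study table (standardized predictors).
#' @param spec a [mebn_spec()].
#' @param plan a [cv_folds()] plan consistent with the table.
#' @param ... sampler settings forwarded to [mebn()].
#' @param n_draws posterior draws per prediction.
#' @param seed master seed.
#' @param in_sample also fit the full table and report in-sample metrics.
#' @return class `mebn_cv`: list with `metrics` (response, in_nrmse, cv_nrmse,
#'   in_acc, cv_acc, plus a `network` row), `cv_records`, `in_records`,
#'   `fold_log` (train/test row indices per fold for leakage auditing), and
#'   `failures`.
#' @export
run_cv <- function(data, spec, plan, ..., n_draws = 100, seed = 1,
                   in_sample = TRUE) {
  stopifnot(inherits(plan, "mebn_folds"))
  responses <- spec$responses
  cv_pred <- list(); fold_log <- list(); failures <- list()
  combos <- unique(plan[c("split", "fold")])
  for (i in seq_len(nrow(combos))) {
    sp <- combos$split[i]; fd <- combos$fold[i]
    sel <- plan$split == sp & plan$fold == fd
    held_subj <- plan$subject_id[sel]
    held_week <- plan$heldout_week[sel][1]
    test_rows <- which(data$subject_id %in% held_subj & data$week == held_week)
    train_rows <- setdiff(seq_len(nrow(data)), test_rows)
    fold_log[[i]] <- list(split = sp, fold = fd, heldout_week = held_week,
                          train_rows = train_rows, test_rows = test_rows)
    if (!length(test_rows)) next
    fit <- tryCatch(
      mebn(data[train_rows, , drop = FALSE], spec, ..., seed = seed + i),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[length(failures) + 1L]] <-
        list(split = sp, fold = fd, message = conditionMessage(fit))
      next
    }
    # held-out rows keep predictors; previous weeks' observed responses give
    # the AR input; the held-out response values themselves are never shown
    ar_context <- data[data$subject_id %in% held_subj, , drop = FALSE]
    ar_context[ar_context$week == held_week, responses] <- NA_real_
    pred <- predict(fit, newdata = ar_context, n_draws = n_draws,
                    seed = seed + i)
    keep <- paste(pred$subject_id, pred$week) %in%
      paste(data$subject_id[test_rows], data$week[test_rows])
    cv_pred[[i]] <- pred[keep, , drop = FALSE]
  }
  cv_pred <- do.call(rbind, cv_pred)

  per_cv <- lapply(responses, function(r) {
    p <- cv_pred[cv_pred$response == r, ]
    obs <- data[[r]][match(paste(p$subject_id, p$week),
                           paste(data$subject_id, data$week))]
    keep <- !is.na(obs)
    data.frame(response = r, cv_nrmse = nrmse(p$mean[keep], obs[keep]),
               stringsAsFactors = FALSE)
  })
  per_cv <- do.call(rbind, per_cv)
  cv_records <- .direction_records(cv_pred, data, responses)
  cv_acc <- direction_accuracy(cv_records)

  in_metrics <- NULL; in_records <- NULL; in_acc <- NULL
  if (in_sample) {
    full <- mebn(data, spec, ..., seed = seed)
    rep_in <- metric_report(full, n_draws = n_draws, seed = seed)
    in_metrics <- rep_in$per_response
    pred_in <- predict(full, n_draws = n_draws, seed = seed)
    in_records <- .direction_records(pred_in, data, responses)
    in_acc <- direction_accuracy(in_records)
  }

  metrics <- data.frame(response = responses, stringsAsFactors = FALSE)
  metrics$in_nrmse <- if (!is.null(in_metrics))
    in_metrics$nrmse[match(responses, in_metrics$response)] else NA_real_
  metrics$cv_nrmse <- per_cv$cv_nrmse[match(responses, per_cv$response)]
  metrics$in_acc <- if (!is.null(in_acc))
    in_acc$accuracy[match(responses, in_acc$group)] else NA_real_
  metrics$cv_acc <- cv_acc$accuracy[match(responses, cv_acc$group)]
  network <- data.frame(response = "network",
                        in_nrmse = mean(metrics$in_nrmse),
                        cv_nrmse = network_nrmse(metrics$cv_nrmse),
                        in_acc = if (!is.null(in_acc))
                          in_acc$accuracy[in_acc$group == "overall"] else NA_real_,
                        cv_acc = cv_acc$accuracy[cv_acc$group == "overall"],
                        stringsAsFactors = FALSE)
  structure(list(metrics = rbind(metrics, network), cv_records = cv_records,
                 in_records = in_records, fold_log = fold_log,
                 failures = failures, plan = plan),
            class = "mebn_cv")
}

#' @export
print.mebn_cv <- function(x, ...) {
  cat(sprintf("Cross-validation over %d fold fits (%d failed)\n",
              length(x$fold_log), length(x$failures)))
  print.data.frame(format(x$metrics, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Baseline adapter harness for the classification comparison
#'
#' Runs an external direction-of-change classifier through the same fold
#' plan as [run_cv()] so its accuracy is directly comparable. The adapter
#' receives the training rows and the test rows (predictors plus the previous
#' observed value in `last_observed`) for one response at a time and must
#' return `"increase"`/`"decrease"` per test row; gradient-boosting or
#' random-forest backends are supplied by the user, not by this package. With
#' `adapter = NULL` the comparison is skipped with a notice.
#'
#' @param data study table.
#' @param plan a [cv_folds()] plan.
#' @param responses responses to classify.
#' @param adapter `function(train, test, response)` or `NULL`.
#' @return a records data frame as in [direction_accuracy()], or `NULL` when
#'   no adapter is given.
#' @export
run_cv_baseline <- function(data, plan, responses, adapter = NULL) {
  if (is.null(adapter)) {
    message("no baseline adapter supplied; comparison skipped")
    return(NULL)
  }
  data <- data[order(data$subject_id, data$week), ]
  grid <- sort(unique(data$week))
  key <- paste(data$subject_id, data$week)
  combos <- unique(plan[c("split", "fold")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- plan$split == combos$split[i] & plan$fold == combos$fold[i]
    held_subj <- plan$subject_id[sel]
    held_week <- plan$heldout_week[sel][1]
    test_rows <- which(data$subject_id %in% held_subj & data$week == held_week)
    if (!length(test_rows)) next
    train <- data[-test_rows, , drop = FALSE]
    for (r in responses) {
      test <- data[test_rows, , drop = FALSE]
      tix <- match(test$week, grid)
      test$last_observed <- data[[r]][match(paste(test$subject_id,
                                                  grid[pmax(tix - 1, 1)]), key)]
      ok <- tix > 1 & !is.na(test$last_observed) & !is.na(test[[r]])
      if (!any(ok)) next
      test_ok <- test[ok, , drop = FALSE]
      pd <- adapter(train, test_ok, r)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = test_ok$subject_id, week = test_ok$week, response = r,
        predicted_direction = pd,
        true_direction = ifelse(test_ok[[r]] > test_ok$last_observed,
                                "increase", "decrease"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname run_cv_baseline
#' @param train,test,response adapter arguments.
#' @export
baseline_always_decrease <- function(train, test, response) {
  rep("decrease", nrow(test))
}
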