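#' Subjects-by-effects table of personal effect means
#'
#' Builds the matrix fed to clustering: one row per subject, one column per
#' (response, personal predictor) pair, each entry the posterior mean of the
#' full personal effect \eqn{\beta + b_k}. Companion arrays carry the 90%
#' interval bounds and the posterior summaries of \eqn{\sigma_b}.
#'
#' @param net a fitted [mebn()].
#' @param predictors restrict to a subset of the personal predictors (e.g.
#'   nutrients only, excluding sex and medication columns).
#' @param include_intercept keep the personal-baseline column; default FALSE,
#'   so columns are predictor effects only.
#' @return class `mebn_effect_table`: list with matrix `mean` (subjects x
#'   effects), matrices `q05`, `q95`, and data frame `sigma_b`.
#' @export
effect_table <- function(net, predictors = NULL, include_intercept = FALSE) {
  stopifnot(inherits(net, "mebn"))
  subjects <- net$locals[[1]]$subjects
  cols <- list(); lo <- list(); hi <- list(); sb <- list()
  for (r in net$spec$responses) {
    loc <- net$locals[[r]]
    keep <- loc$personal
    if (!include_intercept) keep <- setdiff(keep, "(Intercept)")
    if (!is.null(predictors)) keep <- intersect(keep, predictors)
    if (!length(keep)) next
    if (!identical(loc$subjects, subjects))
      stop("locals disagree on the subject set")
    jx <- match(keep, loc$personal)
    beta <- loc$draws$beta[, keep, drop = FALSE]
    for (i in seq_along(keep)) {
      eff <- matrix(loc$draws$b[, , jx[i]],
                    nrow = dim(loc$draws$b)[1]) + beta[, i]  # ndraw x S
      nm <- paste(r, keep[i], sep = ":")
      cols[[nm]] <- colMeans(eff)
      lo[[nm]] <- apply(eff, 2, quantile, 0.05)
      hi[[nm]] <- apply(eff, 2, quantile, 0.95)
      sbd <- loc$draws$sigma_b[, keep[i]]
      sb[[nm]] <- data.frame(response = r, predictor = keep[i],
                             sigma_b_mean = mean(sbd),
                             sigma_b_q05 = quantile(sbd, 0.05),
                             sigma_b_q95 = quantile(sbd, 0.95),
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(cols)) stop("no personal-effect columns selected")
  m <- do.call(cbind, cols)
  rownames(m) <- subjects
  sbdf <- do.call(rbind, sb); rownames(sbdf) <- NULL
  structure(list(mean = m, q05 = do.call(cbind, lo), q95 = do.call(cbind, hi),
                 sigma_b = sbdf, subjects = subjects),
            class = "mebn_effect_table")
}

#' Within-cluster sum-of-squares scan (elbow method)
#'
#' Runs k-means for each candidate number of clusters with multiple seeded
#' restarts (plus a nested warm start from the previous k's best solution, so
#' the WSS curve is non-increasing) and suggests the elbow as the k with the
#' largest second difference of the log-WSS curve. The suggestion is advisory; the
#' curve itself (raw and as a fraction of total SS) is returned for judgment.
#'
#' @param effects a [effect_table()] result or a plain numeric matrix.
#' @param k_range candidate cluster counts.
#' @param seed RNG seed.
#' @param n_restarts random restarts per k.
#' @return class `mebn_elbow`: data frame (k, wss, ratio) with the suggested
#'   k as attribute `suggested`.
#' @export
elbow_scan <- function(effects, k_range = 1:8, seed = 1, n_restarts = 25) {
  m <- if (inherits(effects, "mebn_effect_table")) effects$mean else as.matrix(effects)
  if (min(k_range) < 1 || max(k_range) > nrow(m) - 1 && max(k_range) != nrow(m))
    stop("k_range must lie within [1, subjects]")
  k_range <- sort(k_range)
  set.seed(as.integer(seed))
  tot <- sum(scale(m, scale = FALSE)^2)
  wss <- numeric(length(k_range))
  prev_centers <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1) {
      wss[i] <- tot
      prev_centers <- matrix(colMeans(m), 1)
      next
    }
    if (k == nrow(m)) {
      wss[i] <- 0
      prev_centers <- m
      next
    }
    km <- stats::kmeans(m, centers = k, nstart = n_restarts, iter.max = 50)
    # warm start: previous best centers plus the point farthest from them
    if (!is.null(prev_centers) && nrow(prev_centers) == k - 1) {
      d2 <- apply(m, 1, function(row)
        min(colSums((t(prev_centers) - row)^2)))
      warm <- rbind(prev_centers, m[which.max(d2), ])
      km2 <- tryCatch(stats::kmeans(m, centers = warm, iter.max = 50),
                      error = function(e) NULL)
      if (!is.null(km2) && km2$tot.withinss < km$tot.withinss) km <- km2
    }
    wss[i] <- km$tot.withinss
    prev_centers <- km$centers
  }
  wss <- cummin(wss)  # guard against restart noise; WSS is non-increasing in k
  # elbow: largest second difference of the WSS curve on the log scale
  # (relative curvature), robust to unevenly spaced cluster separations
  suggested <- if (length(k_range) >= 3) {
    d2 <- diff(diff(log(pmax(wss, .Machine$double.eps))))
    k_range[which.max(d2) + 1L]
  } else k_range[length(k_range)]
  structure(data.frame(k = k_range, wss = wss, ratio = wss / tot),
            suggested = suggested, class = c("mebn_elbow", "data.frame"))
}

#' Cluster subjects by their personal-effect profiles
#'
#' Standard k-means on the subjects-by-effects matrix of posterior means,
#' best of `n_restarts` seeded restarts.
#'
#' @param effects a [effect_table()] or numeric matrix.
#' @param k number of clusters.
#' @param seed RNG seed (deterministic result).
#' @param n_restarts random restarts.
#' @return class `mebn_clusters`: list with `labels` (named by subject),
#'   `sizes`, `percent`, `centers`, `wss`, `k`.
#' @export
kmeans_cluster <- function(effects, k, seed = 1, n_restarts = 25) {
  m <- if (inherits(effects, "mebn_effect_table")) effects$mean else as.matrix(effects)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(m)) stop("k exceeds the number of subjects")
  set.seed(as.integer(seed))
  if (k == nrow(m)) {  # singleton clusters; stats::kmeans requires k < n
    km <- list(cluster = seq_len(nrow(m)), size = rep(1L, nrow(m)),
               centers = m, tot.withinss = 0)
  } else {
    km <- stats::kmeans(m, centers = k, nstart = n_restarts, iter.max = 50)
  }
  sizes <- as.integer(km$size)
  structure(list(labels = setNames(km$cluster, rownames(m)),
                 sizes = sizes, percent = 100 * sizes / nrow(m),
                 centers = km$centers, wss = km$tot.withinss, k = k),
            class = "mebn_clusters")
}

#' @export
print.mebn_clusters <- function(x, ...) {
  cat(sprintf("k-means clustering of personal effects: k = %d\n", x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  cluster %d: %d subjects (%.1f%%)\n", i, x$sizes[i],
                x$percent[i]))
  invisible(x)
}

#' Ranked table of the most personally varying effects
#'
#' Rows are (predictor, response) effects sorted by decreasing posterior mean
#' of the inter-subject standard deviation \eqn{\sigma_b}, filtered at a
#' threshold (default 0.10). For each effect the minimum and maximum personal
#' effect \eqn{\beta + b_k} over subjects is reported with its 90% credible
#' interval.
#'
#' @param net a fitted [mebn()].
#' @param threshold retain effects with posterior mean \eqn{\sigma_b} above
#'   this value; `0` keeps all.
#' @param include_intercept rank the personal baseline too; default FALSE.
#' @return data frame: predictor, response, sigma_b (with q05/q95), min/max
#'   personal effect (with bounds), sorted by sigma_b.
#' @export
rank_varying_effects <- function(net, threshold = 0.10,
                                 include_intercept = FALSE) {
  stopifnot(inherits(net, "mebn"))
  et <- effect_table(net, include_intercept = include_intercept)
  sb <- et$sigma_b
  rows <- lapply(seq_len(nrow(sb)), function(i) {
    nm <- paste(sb$response[i], sb$predictor[i], sep = ":")
    means <- et$mean[, nm]
    kmin <- which.min(means); kmax <- which.max(means)
    data.frame(predictor = sb$predictor[i], response = sb$response[i],
               sigma_b = sb$sigma_b_mean[i],
               sigma_b_q05 = sb$sigma_b_q05[i], sigma_b_q95 = sb$sigma_b_q95[i],
               min_effect = means[kmin], min_q05 = et$q05[kmin, nm],
               min_q95 = et$q95[kmin, nm],
               max_effect = means[kmax], max_q05 = et$q05[kmax, nm],
               max_q95 = et$q95[kmax, nm], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$sigma_b), , drop = FALSE]
  out <- out[out$sigma_b > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the effect graph as a weighted signed edge list
#'
#' Edges run predictor -> response with weight the absolute posterior mean
#' effect and sign its direction. `mode = "general"` uses the general
#' coefficients \eqn{\beta}; `mode = "subject"` uses one subject's personal
#' effects \eqn{\beta + b_k}. Keep either the `top_n` largest-weight edges
#' (e.g. the 20 most prominent personal effects) or all above a threshold.
#'
#' @param net a fitted [mebn()].
#' @param mode `"general"` or `"subject"`.
#' @param subject subject id, required for subject mode.
#' @param top_n keep this many largest-|weight| edges.
#' @param threshold keep edges with |weight| above this (applied when
#'   `top_n` is `NULL`; default 0).
#' @param file optional path; writes GraphML for external visualization.
#' @return data frame: predictor, response, effect, weight, sign.
#' @export
export_effect_graph <- function(net, mode = c("general", "subject"),
                                subject = NULL, top_n = NULL, threshold = 0,
                                file = NULL) {
  stopifnot(inherits(net, "mebn"))
  mode <- match.arg(mode)
  rows <- list()
  for (r in net$spec$responses) {
    loc <- net$locals[[r]]
    if (mode == "general") {
      eff <- colMeans(loc$draws$beta)[setdiff(loc$predictors, "(Intercept)")]
    } else {
      if (is.null(subject)) stop("subject required for subject mode")
      pe <- personal_effects(loc, subject)
      pe <- pe[pe$predictor != "(Intercept)", ]
      gen <- colMeans(loc$draws$beta)
      eff <- setNames(rep(NA_real_, length(loc$predictors) - 1),
                      setdiff(loc$predictors, "(Intercept)"))
      eff[names(eff)] <- gen[names(eff)]       # general where not personal
      eff[pe$predictor] <- pe$effect_mean      # beta + b_k where personal
    }
    rows[[r]] <- data.frame(predictor = names(eff), response = r,
                            effect = as.numeric(eff),
                            weight = abs(as.numeric(eff)),
                            sign = sign(as.numeric(eff)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$weight), , drop = FALSE]
  out <- if (!is.null(top_n)) utils::head(out, top_n)
         else out[out$weight > threshold, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) {
    g <- igraph::graph_from_data_frame(
      out[c("predictor", "response", "weight", "sign", "effect")],
      directed = TRUE)
    igraph::write_graph(g, file, format = "graphml")
  }
  out
}
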