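#' Read or write a long-format study table as CSV
#'
#' Column layout: `subject_id`, `week`, then predictor and response columns;
#' missing values as empty cells. On reading, (subject, week) uniqueness is
#' enforced and subjects with an incomplete week grid are flagged with a
#' warning (gaps are allowed).
#'
#' @param file CSV path.
#' @param data a study table.
#' @return `read_study_table` returns the data frame; `write_study_table`
#'   returns `file` invisibly.
#' @export
read_study_table <- function(file) {
  data <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "week") %in% names(data)))
    stop("study table must have 'subject_id' and 'week' columns")
  if (anyDuplicated(data[c("subject_id", "week")]))
    stop("duplicate (subject_id, week) rows")
  grid <- sort(unique(data$week))
  cnt <- table(data$subject_id)
  if (any(cnt < length(grid)))
    warning("subject(s) with missing weeks: ",
            paste(names(cnt)[cnt < length(grid)], collapse = ", "))
  data
}

#' @rdname read_study_table
#' @export
write_study_table <- function(data, file) {
  utils::write.csv(data, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Persist a fitted network as a directory of plain-text files
#'
#' Writes the spec (YAML), one draws CSV per response (columns `chain`,
#' `iter`, then one column per scalar parameter), and a JSON diagnostics
#' summary. `read_network_dir` restores a `mebn` object (draws only; the
#' training table is not persisted).
#'
#' @param net a fitted [mebn()].
#' @param dir target directory (created if needed).
#' @return `write_network_dir` returns `dir` invisibly.
#' @export
write_network_dir <- function(net, dir) {
  stopifnot(inherits(net, "mebn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spec_yaml(net$spec, file.path(dir, "spec.yaml"))
  diag <- list(data_hash = net$data_hash, seed = net$seed)
  for (r in net$spec$responses) {
    loc <- net$locals[[r]]
    flat <- .flatten_draws(loc)
    utils::write.csv(flat, file.path(dir, paste0("draws_", r, ".csv")),
                     row.names = FALSE)
    meta <- list(response = r, family = loc$family, ar1 = loc$ar1,
                 lkj_eta = loc$lkj_eta, predictors = loc$predictors,
                 personal = loc$personal, subjects = loc$subjects,
                 grid = loc$grid, seed = loc$seed, n_obs = loc$n_obs,
                 prior = unclass(loc$prior),
                 rhat = as.list(loc$diagnostics$rhat),
                 ess = as.list(loc$diagnostics$ess),
                 n_chains = loc$diagnostics$n_chains,
                 n_iter = loc$diagnostics$n_iter)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(dir, paste0("meta_", r, ".json")))
  }
  writeLines(jsonlite::toJSON(diag, auto_unbox = TRUE, null = "null"),
             file.path(dir, "network.json"))
  invisible(dir)
}

.flatten_draws <- function(loc) {
  d <- loc$draws
  S <- length(loc$subjects); Q <- length(loc$personal)
  out <- data.frame(chain = d$chain,
                    iter = stats::ave(d$chain, d$chain, FUN = seq_along))
  bcols <- d$beta; colnames(bcols) <- paste0("beta.", colnames(bcols))
  scols <- d$sigma_b; colnames(scols) <- paste0("sigma_b.", colnames(scols))
  out <- cbind(out, bcols, scols)
  if (!is.null(d$u)) {
    u <- d$u; colnames(u) <- paste0("u.", seq_len(ncol(u)))
    out <- cbind(out, u)
  }
  bm <- matrix(d$b, nrow = dim(d$b)[1])
  colnames(bm) <- as.vector(outer(loc$subjects, loc$personal,
                                  function(k, j) paste0("b.", k, ".", j)))
  out <- cbind(out, bm)
  if (!is.null(d$rho)) out$rho <- d$rho
  out$dispersion <- d$dispersion
  out
}

#' @rdname write_network_dir
#' @export
read_network_dir <- function(dir) {
  spec <- read_spec_yaml(file.path(dir, "spec.yaml"))
  netmeta <- jsonlite::fromJSON(file.path(dir, "network.json"))
  locals <- lapply(spec$responses, function(r) {
    meta <- jsonlite::fromJSON(file.path(dir, paste0("meta_", r, ".json")))
    flat <- utils::read.csv(file.path(dir, paste0("draws_", r, ".csv")),
                            check.names = FALSE)
    S <- length(meta$subjects); Q <- length(meta$personal)
    ndraw <- nrow(flat)
    b <- array(0, c(ndraw, S, Q),
               dimnames = list(NULL, meta$subjects, meta$personal))
    for (k in seq_len(S)) for (j in seq_len(Q))
      b[, k, j] <- flat[[paste0("b.", meta$subjects[k], ".", meta$personal[j])]]
    ucols <- grep("^u\\.", names(flat))
    prior <- if (identical(meta$prior$kind, "vague"))
      prior_vague(meta$prior$intercept_scale, meta$prior$slope_scale)
    else prior_rhs(meta$prior$p0, meta$prior$p, meta$prior$n, meta$prior$sigma,
                   meta$prior$nu, meta$prior$slab_scale,
                   meta$prior$intercept_scale)
    structure(list(
      response = r, family = meta$family, prior = prior, ar1 = meta$ar1,
      lkj_eta = meta$lkj_eta, predictors = meta$predictors,
      personal = meta$personal, subjects = meta$subjects, grid = meta$grid,
      draws = list(
        beta = as.matrix(setNames(flat[paste0("beta.", meta$predictors)],
                                  meta$predictors)),
        sigma_b = as.matrix(setNames(flat[paste0("sigma_b.", meta$personal)],
                                     meta$personal)),
        b = b,
        u = if (length(ucols)) as.matrix(flat[ucols]),
        rho = if (meta$ar1) flat$rho,
        dispersion = flat$dispersion, chain = flat$chain),
      diagnostics = list(rhat = unlist(meta$rhat), ess = unlist(meta$ess),
                         n_chains = meta$n_chains, n_iter = meta$n_iter),
      data_hash = netmeta$data_hash, seed = meta$seed, n_obs = meta$n_obs),
      class = "mebn_local")
  })
  net <- mebn_assemble(locals, spec)
  net$seed <- netmeta$seed
  net
}
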