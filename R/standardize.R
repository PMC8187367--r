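#' Standardize predictor columns
#'
#' Centers and scales the given columns to sample mean 0 and sample sd 1, the
#' scale on which general and personal coefficients are directly comparable
#' effect strengths. Binary columns (sex, medication) are standardized like
#' continuous ones; the returned transform record maps effects back to
#' per-category differences and allows exact inversion.
#'
#' @param data a data frame (long-format study table).
#' @param cols character vector of columns to standardize; defaults to all
#'   numeric columns except `subject_id` and `week`.
#' @return a list with elements `data` (transformed table) and `transform`
#'   (class `mebn_transform`: data frame of column, center, scale).
#' @seealso [unstandardize_predictors()], [apply_transform()]
#' @export
standardize_predictors <- function(data, cols = NULL) {
  if (is.null(cols)) {
    num <- vapply(data, is.numeric, logical(1))
    cols <- setdiff(names(data)[num], c("subject_id", "week"))
  }
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  center <- scale <- numeric(length(cols))
  for (i in seq_along(cols)) {
    x <- data[[cols[i]]]
    if (length(unique(x[!is.na(x)])) < 2)
      stop("zero-variance column cannot be standardized: '", cols[i], "'")
    center[i] <- mean(x, na.rm = TRUE)
    scale[i] <- stats::sd(x, na.rm = TRUE)
    data[[cols[i]]] <- (x - center[i]) / scale[i]
  }
  transform <- structure(data.frame(column = cols, center = center,
                                    scale = scale, stringsAsFactors = FALSE),
                         class = c("mebn_transform", "data.frame"))
  list(data = data, transform = transform)
}

#' Invert or re-apply a standardization transform
#'
#' `unstandardize_predictors` maps standardized columns back to the original
#' scale; `apply_transform` puts new raw data on the scale used at fit time
#' (same centers/scales, not re-estimated).
#'
#' @param data a data frame.
#' @param transform a `mebn_transform` record from [standardize_predictors()].
#' @return the transformed data frame.
#' @export
unstandardize_predictors <- function(data, transform) {
  stopifnot(inherits(transform, "mebn_transform"))
  for (i in seq_len(nrow(transform))) {
    cl <- transform$column[i]
    if (cl %in% names(data))
      data[[cl]] <- data[[cl]] * transform$scale[i] + transform$center[i]
  }
  data
}

#' @rdname unstandardize_predictors
#' @export
apply_transform <- function(data, transform) {
  stopifnot(inherits(transform, "mebn_transform"))
  for (i in seq_len(nrow(transform))) {
    cl <- transform$column[i]
    if (cl %in% names(data))
      data[[cl]] <- (data[[cl]] - transform$center[i]) / transform$scale[i]
  }
  data
}
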