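# The temporal grading index (TGI): for each region, the OLS slope of the
# patient-minus-norm property deviation regressed on the norm property
# across time windows. The slope k is the TGI; the intercept b is kept as a
# diagnostic but excluded from prediction features.

#' Fit the deviation-slope model for one region
#'
#' Ordinary least squares of \code{y - x} on \code{x} with intercept, where
#' \code{x} is the healthy-control norm property time course and \code{y}
#' the patient's. Closed-form slope \code{cov(x, y - x) / var(x)} and
#' intercept. When the norm series is (numerically) flat the slope is
#' undefined: the fit is flagged rather than silently zeroed.
#'
#' @param x norm property series over windows (length t >= 3).
#' @param y patient property series, same length.
#' @param var_tol variance tolerance below which x counts as flat.
#' @return list: \code{k} (slope), \code{b} (intercept), \code{defined}
#'   (FALSE for flat norm; k and b are then NA), \code{r2}, \code{resid_sd},
#'   \code{se_k} (the OLS standard error of the slope).
#' @export
tgi_fit <- function(x, y, var_tol = 1e-12) {
  stopifnot(length(x) == length(y))
  t <- length(x)
  if (t < 3L) stop_dim("need at least 3 windows, got %d", t)
  d <- y - x
  vx <- stats::var(x)
  if (!is.finite(vx) || vx <= var_tol) {
    return(list(k = NA_real_, b = NA_real_, defined = FALSE,
                r2 = NA_real_, resid_sd = NA_real_, se_k = NA_real_))
  }
  k <- stats::cov(x, d) / vx
  b <- mean(d) - k * mean(x)
  resid <- d - (k * x + b)
  ss_res <- sum(resid^2)
  ss_tot <- sum((d - mean(d))^2)
  resid_sd <- sqrt(ss_res / (t - 2))
  se_k <- resid_sd / sqrt(vx * (t - 1))
  list(k = k, b = b, defined = TRUE,
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       resid_sd = resid_sd, se_k = se_k)
}

#' Per-region TGI vector for one subject
#'
#' Applies \code{\link{tgi_fit}} column-wise to a patient's property matrix
#' against the norm property matrix (the property computed from the
#' window-wise group-average network stack). Regions with a flat norm
#' series get TGI imputed as 0 -- the conservative "no deviation" value --
#' and are flagged in the diagnostics, keeping the feature dimension fixed
#' across subjects.
#'
#' @param x_patient patient \code{\link{property_matrix}} (t x n).
#' @param x_norm norm \code{property_matrix}, same t, n, property, and
#'   region order.
#' @return object of class \code{tgi_vector}: \code{k}, \code{b} (length n),
#'   \code{property}, \code{subject_id}, data.frame \code{diagnostics}
#'   (defined, r2, resid_sd, se_k per region).
#' @export
tgi_subject <- function(x_patient, x_norm) {
  stopifnot(inherits(x_patient, "property_matrix"),
            inherits(x_norm, "property_matrix"))
  if (!identical(dim(x_patient$data), dim(x_norm$data)))
    stop_dim("patient matrix is %dx%d but norm is %dx%d",
             nrow(x_patient$data), ncol(x_patient$data),
             nrow(x_norm$data), ncol(x_norm$data))
  if (!identical(x_patient$labels, x_norm$labels))
    stop("patient and norm region labels differ", call. = FALSE)
  if (!identical(x_patient$property, x_norm$property))
    stop(sprintf("property mismatch: %s vs %s",
                 x_patient$property, x_norm$property), call. = FALSE)
  n <- ncol(x_norm$data)
  fits <- lapply(seq_len(n), function(j)
    tgi_fit(x_norm$data[, j], x_patient$data[, j]))
  k <- vapply(fits, `[[`, numeric(1L), "k")
  b <- vapply(fits, `[[`, numeric(1L), "b")
  defined <- vapply(fits, `[[`, logical(1L), "defined")
  k[!defined] <- 0
  b[!defined] <- 0
  diag_df <- data.frame(
    region = x_norm$labels,
    defined = defined,
    r2 = vapply(fits, `[[`, numeric(1L), "r2"),
    resid_sd = vapply(fits, `[[`, numeric(1L), "resid_sd"),
    se_k = vapply(fits, `[[`, numeric(1L), "se_k"),
    stringsAsFactors = FALSE)
  structure(list(k = stats::setNames(k, x_norm$labels),
                 b = stats::setNames(b, x_norm$labels),
                 property = x_norm$property,
                 subject_id = x_patient$subject_id,
                 diagnostics = diag_df),
            class = "tgi_vector")
}

#' @export
print.tgi_vector <- function(x, ...) {
  cat(sprintf("<tgi_vector> %s/%s: %d regions (%d undefined), mean k = %.4f\n",
              x$subject_id, x$property, length(x$k),
              sum(!x$diagnostics$defined), mean(x$k)))
  invisible(x)
}

#' Norm property matrix from the healthy-control average stack
#'
#' The norm is computed metric-after-averaging: networks are averaged
#' across controls window-wise first, then the metric is taken on the
#' averaged networks. Metric-before-averaging (mean of per-subject property
#' matrices) is available for sensitivity analysis.
#'
#' @param hc_stacks list of control \code{dfc_stack} objects.
#' @param property,partition,degree_mode as in
#'   \code{\link{dynamic_property_matrix}}.
#' @param order \code{"metric_after_averaging"} (default) or
#'   \code{"metric_before_averaging"}.
#' @return a \code{\link{property_matrix}} with subject_id \code{"HC_mean"}.
#' @export
norm_property <- function(hc_stacks, property, partition = NULL,
                          degree_mode = "count",
                          order = c("metric_after_averaging",
                                    "metric_before_averaging")) {
  order <- match.arg(order)
  if (order == "metric_after_averaging") {
    wh <- group_average_stack(hc_stacks)
    dynamic_property_matrix(wh, property, partition, degree_mode)
  } else {
    mats <- lapply(hc_stacks, dynamic_property_matrix, property = property,
                   partition = partition, degree_mode = degree_mode)
    acc <- Reduce(`+`, lapply(mats, `[[`, "data")) / length(mats)
    property_matrix(acc, property = property, subject_id = "HC_mean",
                    labels = hc_stacks[[1L]]$labels)
  }
}

#' Assemble and standardize the TGI feature matrix
#'
#' Concatenates per-property TGI slopes across regions into a subjects x
#' (properties * n) matrix, then z-scores each column. Standardization
#' statistics (mean, sd) are estimated on \code{standardize_on} rows only --
#' during cross-validation these are the training subjects, so no test-set
#' information leaks into the scaling. Zero-variance columns are set to 0
#' with a warning.
#'
#' @param tgi_sets named list (one entry per property) of lists of
#'   \code{\link{tgi_vector}}s over the same subjects in the same order.
#' @param standardize_on integer row indices used to fit the column means
#'   and sds (default: all rows).
#' @param standardize z-score the columns (default TRUE); when FALSE the
#'   raw slopes are returned.
#' @return a numeric matrix with dimnames; attributes \code{center} and
#'   \code{scale} record the standardization parameters.
#' @export
combine_features <- function(tgi_sets, standardize_on = NULL,
                             standardize = TRUE) {
  stopifnot(is.list(tgi_sets), length(tgi_sets) >= 1L)
  if (is.null(names(tgi_sets)))
    names(tgi_sets) <- vapply(tgi_sets, function(s) s[[1L]]$property, character(1L))
  n_sub <- length(tgi_sets[[1L]])
  ids <- vapply(tgi_sets[[1L]], `[[`, character(1L), "subject_id")
  blocks <- lapply(names(tgi_sets), function(prop) {
    set <- tgi_sets[[prop]]
    if (length(set) != n_sub)
      stop_dim("property '%s' has %d subjects, expected %d", prop, length(set), n_sub)
    ids_p <- vapply(set, `[[`, character(1L), "subject_id")
    if (!identical(ids_p, ids))
      stop("subject order differs across properties", call. = FALSE)
    m <- do.call(rbind, lapply(set, `[[`, "k"))
    colnames(m) <- paste0(prop, ":", names(set[[1L]]$k))
    m
  })
  X <- do.call(cbind, blocks)
  rownames(X) <- ids
  if (!standardize) return(X)
  standardize_features(X, standardize_on)
}

#' Z-score feature columns using statistics from a subject subset
#'
#' @param X numeric feature matrix (subjects x features).
#' @param rows indices whose rows define the column means/sds (default all).
#' @return standardized matrix with \code{center}/\code{scale} attributes.
#' @export
standardize_features <- function(X, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(X))
  mu <- colMeans(X[rows, , drop = FALSE])
  sdv <- apply(X[rows, , drop = FALSE], 2L, stats::sd)
  zero <- !is.finite(sdv) | sdv == 0
  if (any(zero))
    warning(sprintf("%d zero-variance feature column(s) set to 0", sum(zero)),
            call. = FALSE)
  sdv[zero] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  Z[, zero] <- 0
  attr(Z, "center") <- mu
  attr(Z, "scale") <- sdv
  attr(Z, "zero_variance") <- zero
  Z
}
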