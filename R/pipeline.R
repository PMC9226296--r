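# End-to-end convenience wrappers chaining the pipeline stages. Each stage
# is also callable on its own; these wrappers only compose them.

#' Compute dynamic-network TGI features for a whole cohort
#'
#' Chains the stages for already-standardized, filtered time series: build
#' per-subject sliding-window network stacks, form the control-average norm
#' stack, compute the requested property matrices, fit per-region TGI for
#' every patient, and assemble the (unstandardized) patient feature matrix.
#' Feature standardization is deliberately left to the consumer so that
#' cross-validation can fit it on training folds only.
#'
#' @param subjects list of \code{\link{roi_ts}} (filtered, standardized).
#' @param groups character vector ("HC"/"CBP") aligned with
#'   \code{subjects}.
#' @param partition a \code{\link{module_partition}} (needed for "pc").
#' @param window_length,window_step sliding-window parameters in TRs.
#' @param properties metrics to compute, subset of degree/cc/pc.
#' @param degree_mode "strength" (default) or "count". Strength is the
#'   pipeline default because count degree evaluated on the averaged
#'   control network is constant across windows (averaging removes the
#'   zeros negative correlations would leave), which makes the degree
#'   deviation regression degenerate.
#' @param norm_order see \code{\link{norm_property}}.
#' @return list: \code{features} (patients x properties*regions raw TGI
#'   matrix), \code{tgi_sets} (per property, list of \code{tgi_vector}),
#'   \code{norms} (per property \code{property_matrix}),
#'   \code{patient_ids}.
#' @export
cohort_tgi_features <- function(subjects, groups, partition = NULL,
                                window_length = 50L, window_step = 1L,
                                properties = c("degree", "cc", "pc"),
                                degree_mode = "strength",
                                norm_order = "metric_after_averaging") {
  stopifnot(length(subjects) == length(groups))
  is_hc <- groups == "HC"
  if (!any(is_hc)) stop("no control subjects to define the norm", call. = FALSE)
  if (!any(!is_hc)) stop("no patients to compute TGI for", call. = FALSE)
  T <- nrow(subjects[[1L]]$data)
  spec <- sliding_window_indices(T, window_length, window_step,
                                 tr = subjects[[1L]]$tr)
  stacks <- lapply(subjects, build_dfc_stack, spec = spec)
  hc_stacks <- stacks[is_hc]
  pat_stacks <- stacks[!is_hc]
  norms <- lapply(stats::setNames(properties, properties), function(p)
    norm_property(hc_stacks, p, partition, degree_mode, order = norm_order))
  tgi_sets <- lapply(stats::setNames(properties, properties), function(p) {
    lapply(pat_stacks, function(s)
      tgi_subject(dynamic_property_matrix(s, p, partition, degree_mode),
                  norms[[p]]))
  })
  features <- combine_features(tgi_sets, standardize = FALSE)
  list(features = features, tgi_sets = tgi_sets, norms = norms,
       patient_ids = vapply(pat_stacks, `[[`, character(1L), "subject_id"))
}

#' Preprocess one subject: length standardization plus band-pass
#'
#' @param ts a raw \code{\link{roi_ts}}.
#' @param config a \code{\link{default_config}} list.
#' @return a filtered, standardized \code{roi_ts}.
#' @export
preprocess_subject <- function(ts, config = default_config()) {
  ts <- standardize_length(ts, config$long_length, config$target_length,
                           config$drop_initial)
  bandpass_filter(ts, config$band[["low"]], config$band[["high"]],
                  config$filter_order)
}
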