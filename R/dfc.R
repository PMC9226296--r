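# Sliding-window Pearson-correlation network stacks.

#' Sliding-window start indices
#'
#' Half-open windows \code{[start, start + length)} at stride \code{step},
#' 0-based starts. The window count is
#' \code{floor((T - length) / step) + 1}; with T = 240, length 50, step 1
#' this gives the pipeline's 191 windows. A warning (not an error) is raised
#' when the window spans less time than one cycle of \code{f_min}, the
#' regime where windowed correlations become spurious.
#'
#' @param T number of time points.
#' @param length window length in TRs (>= 3).
#' @param step stride in TRs (>= 1).
#' @param tr repetition time (s), used only for the \code{f_min} check.
#' @param f_min lowest retained frequency, Hz.
#' @return list of class \code{window_spec}: \code{length}, \code{step},
#'   integer vector \code{starts}.
#' @export
sliding_window_indices <- function(T, length = 50L, step = 1L, tr = NULL,
                                   f_min = 0.01) {
  if (length < 3L) stop("window length must be >= 3 TRs", call. = FALSE)
  if (length > T) stop_dim("window length %d exceeds T = %d", length, T)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (!is.null(tr) && length * tr < 1 / f_min)
    warning(sprintf("window spans %.0f s < 1/f_min = %.0f s; windowed correlations may be spurious",
                    length * tr, 1 / f_min), call. = FALSE)
  starts <- seq.int(0L, T - length, by = step)
  structure(list(length = as.integer(length), step = as.integer(step),
                 starts = as.integer(starts)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d windows of %d TRs, step %d\n",
              length(x$starts), x$length, x$step))
  invisible(x)
}

#' Build a dynamic functional-connectivity stack
#'
#' For each window, the pairwise Pearson correlation over the window's
#' samples, with negative correlations set to zero and the diagonal
#' (self-connectivity) set to zero. Entries therefore lie in [0, 1] and
#' every slice is symmetric. A region that is constant within a window gets
#' zero connectivity for that window (no evidence of coupling) with a
#' warning, rather than propagating NaN.
#'
#' @param ts a standardized, filtered \code{\link{roi_ts}}.
#' @param spec a \code{\link{sliding_window_indices}} result; defaults to
#'   length 50, step 1 over the series.
#' @param fisher_z apply atanh to positive correlations before storage
#'   (off by default; downstream metrics assume weights in [0, 1]).
#' @return object of class \code{dfc_stack}: array \code{arr} (t x n x n),
#'   \code{window}, \code{labels}, \code{subject_id}.
#' @export
build_dfc_stack <- function(ts, spec = NULL, fisher_z = FALSE) {
  stopifnot(inherits(ts, "roi_ts"))
  T <- nrow(ts$data); n <- ncol(ts$data)
  if (is.null(spec)) spec <- sliding_window_indices(T, tr = ts$tr)
  if (max(spec$starts) + spec$length > T)
    stop_dim("window spec exceeds series length %d", T)
  t_win <- length(spec$starts)
  arr <- array(0, dim = c(t_win, n, n))
  warned <- FALSE
  for (w in seq_len(t_win)) {
    rows <- seq.int(spec$starts[w] + 1L, spec$starts[w] + spec$length)
    seg <- ts$data[rows, , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    cc <- suppressWarnings(stats::cor(seg))
    if (any(sds == 0)) {
      cc[sds == 0, ] <- 0
      cc[, sds == 0] <- 0
      warned <- TRUE
    }
    cc[cc < 0] <- 0
    if (fisher_z) cc <- atanh(pmin(cc, 1 - 1e-12))
    diag(cc) <- 0
    arr[w, , ] <- cc
  }
  if (warned)
    warning(sprintf("constant signal within some windows for %s; affected correlations set to 0",
                    ts$subject_id), call. = FALSE)
  structure(list(arr = arr, window = spec, labels = ts$labels,
                 subject_id = ts$subject_id),
            class = "dfc_stack")
}

#' @export
print.dfc_stack <- function(x, ...) {
  cat(sprintf("<dfc_stack> %s: %d windows x %d x %d regions\n",
              x$subject_id, dim(x$arr)[1L], dim(x$arr)[2L], dim(x$arr)[3L]))
  invisible(x)
}

#' Window-wise group-average network stack
#'
#' Element-wise mean of the subjects' stacks per window; used to form the
#' healthy-control norm \code{W_h} against which patient deviations are
#' measured.
#'
#' @param stacks list of \code{dfc_stack} objects sharing dimensions and
#'   window spec.
#' @return a \code{dfc_stack} labeled \code{"HC_mean"}.
#' @export
group_average_stack <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  d0 <- dim(stacks[[1L]]$arr)
  s0 <- stacks[[1L]]$window
  for (s in stacks) {
    if (!identical(dim(s$arr), d0) ||
        !identical(s$window$starts, s0$starts) ||
        s$window$length != s0$length)
      stop(sprintf("stack for %s has mismatched dimensions or window spec",
                   s$subject_id), call. = FALSE)
  }
  acc <- array(0, dim = d0)
  for (s in stacks) acc <- acc + s$arr
  structure(list(arr = acc / length(stacks), window = s0,
                 labels = stacks[[1L]]$labels, subject_id = "HC_mean"),
            class = "dfc_stack")
}
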