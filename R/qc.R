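# Temporal standardization, band-pass filtering, and motion-based exclusion
# applied before network construction.

#' Harmonize scan length and drop equilibration volumes
#'
#' Acquisitions come in two lengths; long runs are truncated by dropping
#' trailing volumes down to \code{target_length}, then the first
#' \code{drop_initial} volumes are removed for signal equilibration. With
#' the defaults a 305-volume run becomes 245 and then 240; a 245-volume run
#' becomes 240. Already-standardized input (T = target_length -
#' drop_initial) passes through unchanged, so the operation is idempotent.
#'
#' @param ts a \code{\link{roi_ts}}.
#' @param long_length accepted long run length (volumes).
#' @param target_length harmonized length before equilibration dropping.
#' @param drop_initial leading volumes to discard.
#' @param strict when TRUE, input length must be one of
#'   \code{long_length}, \code{target_length}, or the already-standardized
#'   length; otherwise any T >= target_length is truncated.
#' @return a \code{roi_ts} with \code{target_length - drop_initial} rows.
#' @export
standardize_length <- function(ts, long_length = 305L, target_length = 245L,
                               drop_initial = 5L, strict = TRUE) {
  stopifnot(inherits(ts, "roi_ts"))
  T <- nrow(ts$data)
  final_len <- target_length - drop_initial
  if (T == final_len) return(ts)
  if (T < target_length)
    stop_dim("run has %d volumes, fewer than the target length %d", T, target_length)
  if (strict && !(T %in% c(long_length, target_length)))
    stop_dim("run length %d not in the accepted set {%d, %d}",
             T, long_length, target_length)
  m <- ts$data[seq_len(target_length), , drop = FALSE]   # drop trailing
  if (drop_initial > 0)
    m <- m[-seq_len(drop_initial), , drop = FALSE]       # drop leading
  roi_ts(m, tr = ts$tr, labels = ts$labels, subject_id = ts$subject_id)
}

#' Zero-phase band-pass filter per region
#'
#' A Butterworth band-pass (default order 2) applied forward and backward
#' (\code{signal::filtfilt}), giving zero phase distortion; each column is
#' demeaned first, so constant signal maps to (numerically) zero.
#'
#' @param ts a \code{\link{roi_ts}}.
#' @param low,high band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @param order Butterworth design order.
#' @return a filtered \code{roi_ts} of the same shape.
#' @export
bandpass_filter <- function(ts, low = 0.01, high = 0.1, order = 2L) {
  stopifnot(inherits(ts, "roi_ts"))
  fs <- 1 / ts$tr
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band (%g, %g) Hz outside (0, Nyquist = %g)", low, high, nyq),
         call. = FALSE)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  m <- ts$data
  m <- sweep(m, 2L, colMeans(m))
  out <- apply(m, 2L, function(col) signal::filtfilt(bf, col))
  roi_ts(out, tr = ts$tr, labels = ts$labels, subject_id = ts$subject_id)
}

#' Framewise displacement (Power formulation)
#'
#' \code{FD_t = sum |delta trans| + r * sum |delta rot (rad)|} over the three
#' translation and three rotation axes, with rotations converted from
#' degrees to arc length on a sphere of radius \code{head_radius} mm. The
#' first volume has FD 0 by convention.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (degrees).
#' @param head_radius sphere radius in mm.
#' @return numeric vector of length T.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("FD undefined for a single-time-point trace", call. = FALSE)
  if (ncol(motion) != 6L) stop_dim("motion trace must have 6 columns, got %d", ncol(motion))
  if (any(!is.finite(motion))) stop("motion trace contains non-finite values", call. = FALSE)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE] * pi / 180)
  c(0, fd)
}

#' Motion-based subject exclusion
#'
#' A subject is excluded when any absolute translation exceeds
#' \code{trans_thresh} mm, any absolute rotation exceeds \code{rot_thresh}
#' degrees, or mean framewise displacement exceeds \code{fd_thresh} mm. All
#' three diagnostics are always reported.
#'
#' @param motion T x 6 matrix, translations in mm then rotations in degrees.
#' @param trans_thresh,rot_thresh,fd_thresh exclusion thresholds.
#' @param head_radius radius for the FD rotation conversion, mm.
#' @return a list of class \code{qc_decision}: \code{include}, character
#'   \code{reasons} (empty iff included), \code{max_trans}, \code{max_rot},
#'   \code{mean_fd}.
#' @export
motion_qc <- function(motion, trans_thresh = 2, rot_thresh = 2,
                      fd_thresh = 0.2, head_radius = 50) {
  motion <- as.matrix(motion)
  fd <- framewise_displacement(motion, head_radius)
  max_trans <- max(abs(motion[, 1:3]))
  max_rot <- max(abs(motion[, 4:6]))
  mean_fd <- mean(fd)
  reasons <- character(0)
  if (max_trans > trans_thresh) reasons <- c(reasons, "translation")
  if (max_rot > rot_thresh) reasons <- c(reasons, "rotation")
  if (mean_fd > fd_thresh) reasons <- c(reasons, "fd")
  structure(list(include = length(reasons) == 0L, reasons = reasons,
                 max_trans = max_trans, max_rot = max_rot, mean_fd = mean_fd),
            class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  cat(sprintf("<qc_decision> %s  max|trans|=%.3f mm  max|rot|=%.3f deg  mean FD=%.3f mm%s\n",
              if (x$include) "INCLUDE" else "EXCLUDE",
              x$max_trans, x$max_rot, x$mean_fd,
              if (length(x$reasons)) paste0("  [", paste(x$reasons, collapse = ","), "]") else ""))
  invisible(x)
}
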