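# Weighted nodal graph metrics on nonnegative symmetric connectivity
# matrices, and their concatenation across windows into dynamic property
# matrices X (t x n).

check_slice <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop_dim("matrix must be square, got %dx%d", nrow(w), ncol(w))
  if (any(!is.finite(w))) stop("connectivity matrix contains non-finite values", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-10) stop("connectivity matrix must be symmetric", call. = FALSE)
  if (any(w < 0)) stop("negative weights must be removed before metric computation", call. = FALSE)
  diag(w) <- 0
  w
}

#' Nodal degree of one network slice
#'
#' \code{count} mode counts nonzero neighbors (on these matrices zeros arise
#' exactly where correlations were negative, so the count varies across
#' windows); \code{strength} mode sums edge weights.
#'
#' @param w symmetric nonnegative matrix, zero diagonal.
#' @param mode \code{"count"} or \code{"strength"}.
#' @return numeric vector of length n.
#' @export
nodal_degree <- function(w, mode = c("count", "strength")) {
  mode <- match.arg(mode)
  w <- check_slice(w)
  if (mode == "count") rowSums(w > 0) else rowSums(w)
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Edge weights are scaled to [0, 1] by the slice maximum; the clustering of
#' node i is the sum of cube-rooted triangle weight products through i,
#' normalized by \code{k_i (k_i - 1)} with \code{k_i} the nonzero-neighbor
#' count. Nodes with fewer than two neighbors have clustering 0. Invariant
#' to multiplying all weights by a positive constant.
#'
#' @param w symmetric nonnegative matrix, zero diagonal.
#' @return numeric vector in [0, 1].
#' @export
clustering_coefficient <- function(w) {
  w <- check_slice(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, nrow(w)))
  wh <- (w / mx)^(1 / 3)
  cyc <- diag(wh %*% wh %*% wh)     # 2x the triangle intensity through each node
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, cyc / denom, 0)
  unname(out)
}

#' Participation coefficient (strength-based Guimera-Amaral form)
#'
#' \code{PC_i = 1 - sum_m (s_im / s_i)^2} where \code{s_im} is node i's
#' strength into module m and \code{s_i} its total strength. 0 means all
#' strength stays within one module; the maximum for m modules is
#' \code{1 - 1/m}. Isolated nodes (zero strength) are assigned 0.
#'
#' @param w symmetric nonnegative matrix, zero diagonal.
#' @param partition a \code{\link{module_partition}} covering all rows of
#'   \code{w} (matched by position when \code{w} has no dimnames, by label
#'   otherwise); at least 2 modules required.
#' @return numeric vector in [0, 1 - 1/m].
#' @export
participation_coefficient <- function(w, partition) {
  w <- check_slice(w)
  stopifnot(inherits(partition, "module_partition"))
  n <- nrow(w)
  if (!is.null(rownames(w))) {
    idx <- match(rownames(w), partition$region)
    if (anyNA(idx))
      stop(sprintf("region(s) absent from partition: %s",
                   paste(rownames(w)[is.na(idx)], collapse = ", ")), call. = FALSE)
    mods <- partition$module[idx]
  } else {
    if (length(partition) != n)
      stop_dim("partition covers %d regions but matrix has %d nodes",
               length(partition), n)
    mods <- partition$module
  }
  if (length(unique(mods)) < 2L)
    stop("participation coefficient needs >= 2 modules", call. = FALSE)
  mod_f <- factor(mods)
  # strength of each node into each module: n x m
  agg <- t(rowsum(w, mod_f))        # rows: nodes, cols: modules
  s <- rowSums(agg)
  frac2 <- (agg / ifelse(s > 0, s, 1))^2
  out <- ifelse(s > 0, 1 - rowSums(frac2), 0)
  unname(out)
}

#' Construct a dynamic property matrix
#'
#' @param data t x n numeric matrix (windows down rows, regions across).
#' @param property one of \code{"degree"}, \code{"cc"}, \code{"pc"} (or any
#'   label for synthetic use).
#' @param subject_id subject identifier.
#' @param labels region labels.
#' @return object of class \code{property_matrix}.
#' @export
property_matrix <- function(data, property, subject_id = "subject",
                            labels = NULL) {
  data <- as.matrix(data)
  if (is.null(labels)) {
    labels <- colnames(data)
    if (is.null(labels)) labels <- paste0("R", seq_len(ncol(data)))
  }
  colnames(data) <- labels
  structure(list(data = data, property = property, subject_id = subject_id,
                 labels = labels),
            class = "property_matrix")
}

#' @export
print.property_matrix <- function(x, ...) {
  cat(sprintf("<property_matrix> %s/%s: %d windows x %d regions\n",
              x$subject_id, x$property, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Apply a nodal metric slice-wise over a network stack
#'
#' Produces the dynamic property matrix \code{X} (t x n): one row per
#' window, one column per region, metric applied independently per slice.
#'
#' @param stack a \code{\link{build_dfc_stack}} result.
#' @param property \code{"degree"}, \code{"cc"}, or \code{"pc"}.
#' @param partition required for \code{"pc"}.
#' @param degree_mode passed to \code{\link{nodal_degree}}.
#' @return a \code{\link{property_matrix}}.
#' @export
dynamic_property_matrix <- function(stack, property = c("degree", "cc", "pc"),
                                    partition = NULL, degree_mode = "count") {
  stopifnot(inherits(stack, "dfc_stack"))
  property <- match.arg(property)
  if (property == "pc") {
    if (is.null(partition))
      stop("participation coefficient requires a module partition", call. = FALSE)
    idx <- match(stack$labels, partition$region)
    if (anyNA(idx))
      stop(sprintf("region(s) absent from partition: %s",
                   paste(stack$labels[is.na(idx)], collapse = ", ")), call. = FALSE)
    partition <- module_partition(stack$labels, partition$module[idx])
  }
  t_win <- dim(stack$arr)[1L]
  n <- dim(stack$arr)[2L]
  X <- matrix(0, t_win, n)
  for (w in seq_len(t_win)) {
    slice <- stack$arr[w, , ]
    X[w, ] <- switch(property,
                     degree = nodal_degree(slice, mode = degree_mode),
                     cc = clustering_coefficient(slice),
                     pc = participation_coefficient(slice, partition))
  }
  property_matrix(X, property = property, subject_id = stack$subject_id,
                  labels = stack$labels)
}
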