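# Tabular I/O for the pipeline. All tables are tab-separated with a header
# row, decimal point, no thousands separators. Time runs down rows in ROI
# time-series files (T rows, n region columns); the reader transposes only
# when asked explicitly.

#' Construct a parcellated ROI time-series object
#'
#' @param data numeric T x n matrix, rows = time points, columns = regions.
#' @param tr repetition time in seconds.
#' @param labels character vector of n region labels (defaults to column
#'   names or \code{R1..Rn}).
#' @param subject_id identifier carried through the pipeline.
#' @return an object of class \code{roi_ts}.
#' @export
roi_ts <- function(data, tr, labels = NULL, subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric", call. = FALSE)
  if (any(!is.finite(data))) stop("time-series data contains non-finite values", call. = FALSE)
  if (is.null(labels)) {
    labels <- colnames(data)
    if (is.null(labels)) labels <- paste0("R", seq_len(ncol(data)))
  }
  if (length(labels) != ncol(data))
    stop_dim("expected %d region labels, got %d", ncol(data), length(labels))
  if (anyDuplicated(labels)) stop("region labels must be unique", call. = FALSE)
  stopifnot(is.numeric(tr), tr > 0)
  colnames(data) <- labels
  structure(list(data = data, tr = tr, labels = labels, subject_id = subject_id),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject=%s  T=%d time points x n=%d regions  TR=%g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Read a region-by-time table from a delimited text file
#'
#' Expects a tab-separated file with a header row of region labels and one
#' row per time point. Ragged rows raise a format error; any non-numeric
#' cell raises a parse error naming its (row, column) position. Columns with
#' zero variance are kept but flagged with a warning, since constant signal
#' usually indicates an extraction problem upstream.
#'
#' @param path file path.
#' @param tr repetition time in seconds.
#' @param labels optional region labels overriding the header.
#' @param subject_id subject identifier (defaults to the file stem).
#' @param transpose set TRUE if the file stores regions down rows and time
#'   across columns; never guessed from the shape.
#' @return a \code{\link{roi_ts}}.
#' @export
read_roi_table <- function(path, tr, labels = NULL,
                           subject_id = sub("\\.[^.]*$", "", basename(path)),
                           transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged rows in %s: field counts %s", path,
                 paste(unique(nf), collapse = ", ")), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow = nrow(df)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, column %d ('%s') in %s",
                 bad[["row"]], bad[["col"]],
                 as.matrix(df)[bad[["row"]], bad[["col"]]], path),
         call. = FALSE)
  }
  colnames(m) <- colnames(df)
  if (transpose) {
    m <- t(m)
    colnames(m) <- NULL
  }
  v <- apply(m, 2L, stats::var)
  if (any(v == 0))
    warning(sprintf("constant signal in %d region column(s) of %s",
                    sum(v == 0), basename(path)), call. = FALSE)
  roi_ts(m, tr = tr, labels = labels, subject_id = subject_id)
}

#' Write an ROI time-series (or any numeric table) as TSV
#'
#' Values are written with 17 significant digits so a read round-trips to
#' full double precision.
#'
#' @param x a \code{roi_ts} or numeric matrix with column names.
#' @param path output file path.
#' @export
write_roi_table <- function(x, path) {
  m <- if (inherits(x, "roi_ts")) x$data else as.matrix(x)
  txt <- apply(m, 2L, function(col) formatC(col, digits = 17, format = "g"))
  txt <- matrix(trimws(txt), nrow = nrow(m), dimnames = dimnames(m))
  utils::write.table(txt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a region-to-module partition
#'
#' @param region character vector of region labels.
#' @param module character vector (same length) of module names.
#' @return an object of class \code{module_partition}.
#' @export
module_partition <- function(region, module) {
  region <- as.character(region)
  module <- as.character(module)
  if (length(region) != length(module))
    stop_dim("region and module vectors differ in length (%d vs %d)",
             length(region), length(module))
  if (anyDuplicated(region))
    stop(sprintf("duplicate region(s) in partition: %s",
                 paste(unique(region[duplicated(region)]), collapse = ", ")),
         call. = FALSE)
  structure(list(region = region, module = module,
                 modules = unique(module)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d regions in %d modules: %s\n",
              length(x$region), length(x$modules),
              paste(x$modules, collapse = ", ")))
  invisible(x)
}

#' @export
length.module_partition <- function(x) length(x$region)

#' Read a two-column region/module partition table
#'
#' @param path TSV with header and columns \code{region}, \code{module}.
#' @param regions optional character vector of the atlas's full region set;
#'   when given, the table must cover it exactly (unassigned regions are an
#'   error listing the missing labels).
#' @return a \code{\link{module_partition}}.
#' @export
read_partition_table <- function(path, regions = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L)
    stop("partition table needs two columns: region, module", call. = FALSE)
  p <- module_partition(df[[1L]], df[[2L]])
  if (!is.null(regions)) {
    missing <- setdiff(regions, p$region)
    if (length(missing))
      stop(sprintf("partition leaves %d region(s) unassigned: %s",
                   length(missing),
                   paste(utils::head(missing, 10L), collapse = ", ")),
           call. = FALSE)
    keep <- match(regions, p$region)
    p <- module_partition(regions, p$module[keep])
  }
  p
}

#' Write a partition table as TSV
#' @param partition a \code{module_partition}.
#' @param path output path.
#' @export
write_partition_table <- function(partition, path) {
  utils::write.table(data.frame(region = partition$region,
                                module = partition$module),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Collects the analysis parameters in one list: sliding-window length and
#' step (TRs), repetition time (s), band-pass edges (Hz), motion-exclusion
#' thresholds, the metric set, the cross-validation protocol, and the master
#' seed. Window length 50 TR at TR = 2.5 s spans 125 s, longer than one
#' cycle of the 0.01 Hz lower band edge would require divided by the usual
#' safeguard; a warning is raised downstream when length * tr < 1 / f_min.
#'
#' @param ... overrides for any default entry.
#' @return a named list of class \code{run_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    window_length = 50L, window_step = 1L, tr = 2.5,
    band = c(low = 0.01, high = 0.10), filter_order = 2L,
    trans_thresh = 2, rot_thresh = 2, fd_thresh = 0.2, head_radius = 50,
    long_length = 305L, target_length = 245L, drop_initial = 5L,
    metrics = c("degree", "cc", "pc"), degree_mode = "strength",
    fisher_z = FALSE, norm_order = "metric_after_averaging",
    cv_k = 5L, cv_repeats = 10L, inner_folds = 5L,
    lasso_grid = seq(0.10, 1, by = 0.05),
    bias_adjust = TRUE, target_scale = "raw",
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  if (cfg$window_length < 3L) stop("window_length must be >= 3", call. = FALSE)
  nyq <- 1 / (2 * cfg$tr)
  if (!(cfg$band[["low"]] > 0 && cfg$band[["low"]] < cfg$band[["high"]] &&
        cfg$band[["high"]] < nyq))
    stop(sprintf("band must satisfy 0 < low < high < Nyquist (%g Hz)", nyq),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a run manifest
#'
#' Records the configuration, seed, and md5 digests of the input files so a
#' deterministic stage can be re-executed bit-identically.
#'
#' @param config a \code{run_config}.
#' @param inputs character vector of input file paths.
#' @param path output path (plain-text key:value lines).
#' @export
write_manifest <- function(config, inputs, path) {
  lines <- c(sprintf("timestamp\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("seed\t%d", as.integer(config$seed)),
             vapply(names(config), function(k) {
               sprintf("config.%s\t%s", k, paste(format(config[[k]]), collapse = ","))
             }, character(1L)))
  if (length(inputs)) {
    md5 <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("input\t%s\t%s", inputs, md5))
  }
  writeLines(lines, path)
  invisible(path)
}
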