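# Group statistics: covariate-adjusted two-sample tests, Pearson
# association, 2x2 chi-square, and Benjamini-Hochberg FDR correction.

stat_result <- function(statistic, p, df = NA_real_, estimate = NA_real_,
                        direction = NA_real_, method = "") {
  structure(list(statistic = statistic, p = p, df = df, estimate = estimate,
                 direction = direction, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: stat = %.4f, df = %s, p = %.4g\n",
              x$method, x$statistic, format(x$df), x$p))
  invisible(x)
}

#' Covariate-adjusted two-sample test
#'
#' The group effect is the coefficient of the group indicator in an OLS of
#' the values on group plus covariates (algebraically identical to ANCOVA).
#' With no covariates this reduces exactly to the classic pooled-variance
#' two-sample t-test.
#'
#' @param values numeric vector, one value per subject.
#' @param group two-level factor or character vector.
#' @param covariates optional numeric matrix or data.frame of covariates
#'   (factors allowed in a data.frame).
#' @return a \code{stat_result}: t statistic for the group term, its p and
#'   df, and \code{estimate} = adjusted group difference (second level minus
#'   first).
#' @export
covaried_group_test <- function(values, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  if (any(table(group) == 0L)) stop("both groups must be nonempty", call. = FALSE)
  df0 <- data.frame(.value = values, .group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df0 <- cbind(df0, covariates)
  }
  fml <- stats::as.formula(paste(".value ~ .group",
                                 if (!is.null(covariates))
                                   paste("+", paste(sprintf("`%s`", names(covariates)),
                                                    collapse = " + ")) else ""))
  fit <- stats::lm(fml, data = df0)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  row <- grep("^\\.group", rownames(sm))
  stat_result(statistic = sm[row, "t value"], p = sm[row, "Pr(>|t|)"],
              df = fit$df.residual, estimate = sm[row, "Estimate"],
              direction = sign(sm[row, "Estimate"]),
              method = sprintf("group t-test (%s covariates)",
                               if (is.null(covariates)) "no" else ncol(covariates)))
}

#' Pearson correlation with its t-transform p-value
#'
#' @param a,b numeric vectors, length >= 3, both nonconstant.
#' @return a \code{stat_result} with \code{estimate} = r.
#' @export
pearson_association <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "pearson")
  stat_result(statistic = unname(ct$statistic), p = ct$p.value,
              df = unname(ct$parameter), estimate = unname(ct$estimate),
              direction = sign(unname(ct$estimate)), method = "Pearson correlation")
}

#' Chi-square test on a 2x2 contingency table
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return a \code{stat_result} with df = 1.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_dim("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: chi-square undefined", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  stat_result(statistic = unname(ct$statistic), p = ct$p.value, df = 1,
              method = sprintf("chi-square%s", if (correct) " (Yates)" else ""))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure at level \code{q}: adjusted values are the monotone BH
#' q-values; the rejection mask marks adjusted values <= q.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param q target false-discovery rate.
#' @return list: logical \code{reject}, numeric \code{q_values}.
#' @export
fdr_correct <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  qv <- stats::p.adjust(pvalues, method = "BH")
  list(reject = qv <= q, q_values = qv)
}
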