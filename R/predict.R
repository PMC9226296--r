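# Pain-intensity regression: linear SVR, lasso, and elastic net with
# grid-searched hyperparameters, repeated k-fold cross-validation scored by
# MSE, and a training-set bias adjustment of the predictions.
#
# Objectives (unpenalized intercept b throughout):
#   svr_linear : eps-insensitive linear regression with budget C
#   lasso      : (1/2n) ||y - Xb||^2 + lambda * ||beta||_1
#   elastic_net: (1/2n) ||y - Xb||^2 + lambda * ||beta||_1 + alpha * ||beta||_2^2
# The squared error is per-sample (the convention of the standard lasso
# solvers, under which a lambda grid like {0.1 .. 1} spans weak to
# mean-collapsing penalties regardless of n); the L2 term is the squared
# norm, so alpha = 0 reduces the elastic net exactly to the lasso.

# glmnet minimizes (1/2n)RSS + lam_g[(1-a_g)/2 ||b||_2^2 + a_g ||b||_1].
# Matching terms against RSS + lambda ||b||_1 + alpha ||b||_2^2 gives
# lam_g a_g = lambda/(2n) and lam_g (1-a_g) = 2 alpha/(2n) -- up to one
# subtlety: glmnet rescales y to unit (population) sd internally, which
# leaves the 1-homogeneous L1 term invariant but shrinks the effective L2
# penalty by sd(y). The L2 target is therefore pre-multiplied by sd_n(y).
glmnet_map <- function(lambda, alpha, n, y) {
  sy <- sqrt(mean((y - mean(y))^2))
  l2 <- alpha * sy
  tot <- lambda + 2 * l2
  list(lambda = tot / (2 * n),
       alpha = if (tot > 0) lambda / tot else 1)
}

#' Fit one regression model family at fixed hyperparameters
#'
#' @param family \code{"svr_linear"}, \code{"lasso"}, or
#'   \code{"elastic_net"}.
#' @param X numeric subjects x features matrix (typically standardized TGI
#'   features).
#' @param y numeric target vector (VAS).
#' @param hyper named list: \code{C}, \code{epsilon} for SVR;
#'   \code{lambda} for lasso; \code{lambda}, \code{alpha} for elastic net
#'   (penalties on the per-sample squared-error scale; see the file-top
#'   objective definitions).
#' @return object of class \code{fitted_model}: \code{weights},
#'   \code{intercept}, \code{family}, \code{hyper}.
#' @export
fit_model <- function(family = c("lasso", "elastic_net", "svr_linear"),
                      X, y, hyper = list()) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in features or targets", call. = FALSE)
  if (nrow(X) != length(y))
    stop_dim("X has %d rows but y has length %d", nrow(X), length(y))
  if (nrow(X) < 2L) stop("need at least 2 subjects", call. = FALSE)
  n <- nrow(X)
  if (family == "svr_linear") {
    C <- hyper$C %||% 1
    eps <- hyper$epsilon %||% 0.1
    stopifnot(C > 0, eps >= 0)
    fit <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                      cost = C, epsilon = eps, scale = FALSE,
                      tolerance = 1e-6)
    w <- drop(t(fit$coefs) %*% fit$SV)
    # svm() may drop all-zero columns from SV; re-expand to full width
    weights <- numeric(ncol(X))
    names(weights) <- colnames(X)
    if (!is.null(colnames(fit$SV))) {
      weights[colnames(fit$SV)] <- w
    } else weights[] <- w
    b <- -fit$rho
  } else {
    lambda <- hyper$lambda %||% 0
    alpha <- if (family == "elastic_net") hyper$alpha %||% 0 else 0
    stopifnot(lambda >= 0, alpha >= 0)
    # internally the solvers work on the summed-RSS scale
    lam_rss <- 2 * n * lambda
    alp_rss <- 2 * n * alpha
    if (stats::var(y) == 0) {
      weights <- numeric(ncol(X)); b <- mean(y)
    } else if (lambda + alpha == 0) {
      cf <- stats::lm.fit(cbind(1, X), y)$coefficients
      cf[is.na(cf)] <- 0
      weights <- cf[-1L]; b <- cf[[1L]]
    } else {
      g <- glmnet_map(lam_rss, alp_rss, n, y)
      # a short decreasing path ending at the target improves convergence;
      # the last path entry is the requested point, read off directly
      path <- g$lambda * c(16, 8, 4, 2, 1)
      fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = g$alpha,
                            lambda = path, standardize = FALSE,
                            intercept = TRUE, thresh = 1e-12, maxit = 1e6)
      last <- length(fit$lambda)
      weights <- as.numeric(fit$beta[, last])
      b <- fit$a0[[last]]
      pol <- polish_enet(X, y, weights, b, lam_rss, alp_rss)
      weights <- pol$w; b <- pol$b
    }
    names(weights) <- colnames(X)
  }
  structure(list(weights = weights, intercept = unname(b), family = family,
                 hyper = hyper),
            class = "fitted_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact coordinate-descent refinement of the penalized least-squares
# solution RSS + lambda ||w||_1 + alpha ||w||_2^2 (unpenalized intercept),
# run from the glmnet warm start until coordinate updates stall. Drives the
# subgradient (KKT) residual to solver precision.
polish_enet <- function(X, y, w, b, lambda, alpha, tol = 1e-13,
                        max_sweeps = 200L) {
  xs <- colSums(X^2)
  r <- y - drop(X %*% w) - b
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    bnew <- b + mean(r)
    r <- r - (bnew - b); delta <- max(delta, abs(bnew - b)); b <- bnew
    for (j in seq_along(w)) {
      if (xs[j] == 0) next
      z <- sum(X[, j] * r) + xs[j] * w[j]
      wj <- sign(z) * max(abs(z) - lambda / 2, 0) / (xs[j] + alpha)
      if (wj != w[j]) {
        r <- r - X[, j] * (wj - w[j])
        delta <- max(delta, abs(wj - w[j]))
        w[j] <- wj
      }
    }
    if (delta < tol) break
  }
  list(w = w, b = b)
}

#' @export
predict.fitted_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$weights) + object$intercept
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s: %d features, %d nonzero weights, intercept %.4f\n",
              x$family, length(x$weights), sum(x$weights != 0), x$intercept))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' Lasso uses the printed grid lambda in {0.10, 0.15, ..., 1}. SVR and
#' elastic net use a two-step search: a coarse logarithmic grid (9 points
#' per axis; C in 2^-5..2^5, epsilon in 0.01..1, elastic-net lambda in
#' 0.01..1, alpha in 0..1), then a fine 9-point linear grid spanning the two
#' coarse neighbors of the optimum on each axis.
#'
#' @param family model family.
#' @return a data.frame, one row per coarse grid point.
#' @export
default_grid <- function(family = c("lasso", "elastic_net", "svr_linear")) {
  family <- match.arg(family)
  switch(family,
         lasso = data.frame(lambda = seq(0.10, 1, by = 0.05)),
         elastic_net = expand.grid(
           lambda = 10^seq(log10(0.01), 0, length.out = 9),
           alpha = seq(0, 1, length.out = 9)),
         svr_linear = expand.grid(
           C = 2^seq(-5, 5, length.out = 9),
           epsilon = 10^seq(log10(0.01), 0, length.out = 9)))
}

# Inner-CV mean MSE of one hyperparameter point.
inner_cv_mse <- function(family, X, y, hyper, folds) {
  mses <- vapply(seq_len(max(folds)), function(f) {
    tr <- folds != f; te <- !tr
    if (sum(te) == 0L) return(NA_real_)
    fit <- fit_model(family, X[tr, , drop = FALSE], y[tr], hyper)
    mean((predict(fit, X[te, , drop = FALSE]) - y[te])^2)
  }, numeric(1L))
  mean(mses, na.rm = TRUE)
}

fold_assignment <- function(n, k) {
  if (k > n) stop_dim("k = %d folds exceed %d subjects", k, n)
  if (n < 2 * k) {
    # guard against degenerate inner folds with < 2 training subjects
    sizes <- table(rep(seq_len(k), length.out = n))
    if (any(n - sizes < 2)) stop("degenerate folds: < 2 training subjects", call. = FALSE)
  }
  sample(rep(seq_len(k), length.out = n))
}

# Inner-CV scores for a whole grid. For lasso / elastic net all lambda
# values sharing an alpha are scored from a single glmnet path per fold
# (the cv.glmnet strategy); SVR points are fitted one by one.
score_grid <- function(family, X, y, grid, folds) {
  if (family == "svr_linear") {
    return(vapply(seq_len(nrow(grid)), function(i)
      inner_cv_mse(family, X, y, as.list(grid[i, , drop = FALSE]), folds),
      numeric(1L)))
  }
  scores <- rep(NA_real_, nrow(grid))
  alphas <- if ("alpha" %in% names(grid)) grid$alpha else rep(0, nrow(grid))
  p <- ncol(X)
  for (a in unique(alphas)) {
    rows <- which(alphas == a)
    lams <- grid$lambda[rows]
    se <- matrix(NA_real_, length(rows), max(folds))
    for (f in seq_len(max(folds))) {
      tr <- folds != f; te <- !tr
      if (sum(te) == 0L) next
      # The unpenalized intercept is profiled out by centering, then the
      # ridge term is absorbed by data augmentation (sqrt(alpha) * I rows
      # with zero response), reducing every alpha group to one lasso path.
      xm <- colMeans(X[tr, , drop = FALSE]); ym <- mean(y[tr])
      if (stats::var(y[tr]) == 0) {
        # constant training targets: every penalized fit predicts the mean
        se[, f] <- mean((ym - y[te])^2)
        next
      }
      n_tr <- sum(tr)
      Xa <- sweep(X[tr, , drop = FALSE], 2L, xm); ya <- y[tr] - ym
      if (a > 0) {
        Xa <- rbind(Xa, diag(sqrt(2 * n_tr * a), p))
        ya <- c(ya, rep(0, p))
      }
      na <- nrow(Xa)
      lam_g <- lams * n_tr / na
      path <- sort(unique(c(max(lam_g) * c(16, 8, 4, 2), lam_g)),
                   decreasing = TRUE)
      fit <- glmnet::glmnet(Xa, ya, family = "gaussian", alpha = 1,
                            lambda = path, standardize = FALSE,
                            intercept = FALSE, thresh = 1e-10, maxit = 1e6)
      Xte_c <- sweep(X[te, , drop = FALSE], 2L, xm)
      pr <- glmnet::predict.glmnet(fit, Xte_c, s = lam_g) + ym
      se[, f] <- colMeans((pr - y[te])^2)
    }
    scores[rows] <- rowMeans(se, na.rm = TRUE)
  }
  scores
}

refine_axis <- function(grid_vals, best, n_fine = 9L) {
  u <- sort(unique(grid_vals))
  i <- match(best, u)
  lo <- if (i > 1L) u[i - 1L] else u[i]
  hi <- if (i < length(u)) u[i + 1L] else u[i]
  sort(unique(seq(lo, hi, length.out = n_fine)))
}

#' Hyperparameter grid search by inner cross-validation
#'
#' Lasso: exhaustive over its lambda grid. SVR and elastic net: two-step --
#' the coarse grid locates the best region, then a fine linear grid between
#' the coarse optimum's neighbors refines it. Selection minimizes inner-CV
#' mean MSE; ties break deterministically to the smallest hyperparameters
#' (first axis, then second).
#'
#' @param family model family.
#' @param X,y training features and targets.
#' @param inner_folds inner CV fold count.
#' @param grid optional coarse grid (data.frame) overriding
#'   \code{\link{default_grid}}.
#' @param seed seed for the inner fold assignment.
#' @return list: \code{hyper} (named list of the selected point),
#'   \code{score} (its inner-CV MSE), \code{table} (all evaluated points).
#' @export
grid_search <- function(family, X, y, inner_folds = 5L, grid = NULL,
                        seed = 1L) {
  family <- match.arg(family, c("lasso", "elastic_net", "svr_linear"))
  if (is.null(grid)) grid <- default_grid(family)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  X <- as.matrix(X)
  folds <- with_local_seed(derive_seed(seed, "innerfolds"),
                           fold_assignment(nrow(X), inner_folds))
  # sort so which.min's first-index rule implements the tie-break
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  scores <- score_grid(family, X, y, grid, folds)
  best <- as.list(grid[which.min(scores), , drop = FALSE])
  tab <- cbind(grid, mse = scores)
  if (family != "lasso" && nrow(grid) > 1L) {
    fine <- expand.grid(lapply(stats::setNames(names(grid), names(grid)),
                               function(a) refine_axis(grid[[a]], best[[a]])))
    fine <- fine[do.call(order, as.list(fine)), , drop = FALSE]
    fscores <- score_grid(family, X, y, fine, folds)
    if (min(fscores) < min(scores)) {
      best <- as.list(fine[which.min(fscores), , drop = FALSE])
    }
    tab <- rbind(tab, cbind(fine, mse = fscores))
  }
  list(hyper = lapply(best, unname), score = min(tab$mse), table = tab)
}

#' Fit the prediction-bias model on training subjects
#'
#' The signed error \code{delta_i = pred_i - real_i} is regressed on the
#' real target: \code{delta = mu * real + phi}. Subtracting the fitted
#' offset \code{mu * Omega + phi} from a prediction removes the
#' regression-to-the-mean bias of penalized predictors.
#'
#' @param train_predictions,train_targets numeric vectors over the training
#'   subjects; targets must not be constant.
#' @return list of class \code{bias_model}: \code{mu}, \code{phi}.
#' @export
bias_adjust_fit <- function(train_predictions, train_targets) {
  stopifnot(length(train_predictions) == length(train_targets))
  if (length(train_targets) < 2L || stats::var(train_targets) == 0)
    stop("bias model undefined: constant training targets", call. = FALSE)
  delta <- train_predictions - train_targets
  mu <- stats::cov(delta, train_targets) / stats::var(train_targets)
  phi <- mean(delta) - mu * mean(train_targets)
  structure(list(mu = mu, phi = phi), class = "bias_model")
}

#' Apply the bias adjustment to a prediction
#'
#' \code{corrected = prediction - (mu * omega + phi)}, where \code{omega} is
#' the subject's real pain intensity. Using the test subject's own target
#' here follows the published scheme and is an acknowledged circularity;
#' disable bias adjustment to remove all test-target usage.
#'
#' @param prediction raw model prediction(s).
#' @param omega real target value(s) for the same subject(s).
#' @param model a \code{\link{bias_adjust_fit}} result.
#' @return adjusted prediction(s).
#' @export
bias_adjust_apply <- function(prediction, omega, model) {
  prediction - (model$mu * omega + model$phi)
}

#' Repeated k-fold cross-validated prediction
#'
#' Per repeat, a fresh seeded shuffle assigns subjects to k folds. Within
#' each fold, feature standardization, hyperparameter grid search, model
#' fitting and the bias model all use training subjects only; test MSE is
#' computed on bias-adjusted predictions (raw predictions when
#' \code{bias_adjust = FALSE}). The summary is the mean and sd of the
#' repeat-level mean MSEs.
#'
#' @param X raw (unstandardized) subjects x features matrix.
#' @param y target vector.
#' @param family model family.
#' @param k outer folds (default 5).
#' @param repeats outer repetitions (default 10).
#' @param seed master seed; identical seeds give identical results.
#' @param grid optional coarse grid for \code{\link{grid_search}}.
#' @param inner_folds inner CV folds for the grid search.
#' @param bias_adjust apply the training-set bias adjustment (default TRUE).
#' @param standardize z-score features within each training fold.
#' @return object of class \code{cv_result}: data.frame \code{folds} (one
#'   row per repeat x fold with hyperparameters and MSE), data.frame
#'   \code{predictions} (per repeat and subject: raw and adjusted), list
#'   \code{summary} (\code{mean_mse}, \code{sd_mse} over repeat means),
#'   vector \code{mean_abs_weight} (mean |weight| per feature over folds).
#' @export
repeated_kfold <- function(X, y, family = "lasso", k = 5L, repeats = 10L,
                           seed = 1L, grid = NULL, inner_folds = 5L,
                           bias_adjust = TRUE, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop_dim("k = %d folds exceed %d subjects", k, n)
  fold_rows <- list(); pred_rows <- list()
  wsum <- numeric(ncol(X)); wcount <- 0L
  repeat_means <- numeric(repeats)
  for (r in seq_len(repeats)) {
    folds <- with_local_seed(derive_seed(seed, "outerfolds", r),
                             fold_assignment(n, k))
    fold_mses <- numeric(k)
    for (f in seq_len(k)) {
      tr <- which(folds != f); te <- which(folds == f)
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (standardize) {
        Ztr <- suppressWarnings(standardize_features(Xtr))
        ctr <- attr(Ztr, "center"); scl <- attr(Ztr, "scale")
        zv <- attr(Ztr, "zero_variance")
        Zte <- sweep(sweep(Xte, 2L, ctr), 2L, scl, "/")
        Zte[, zv] <- 0
      } else { Ztr <- Xtr; Zte <- Xte }
      gs <- grid_search(family, Ztr, y[tr], inner_folds = inner_folds,
                        grid = grid, seed = derive_seed(seed, "inner", r * 1000L + f))
      fit <- fit_model(family, Ztr, y[tr], gs$hyper)
      wsum <- wsum + abs(fit$weights); wcount <- wcount + 1L
      pr_tr <- predict(fit, Ztr)
      pr_te <- predict(fit, Zte)
      adj <- pr_te
      if (bias_adjust) {
        bm <- bias_adjust_fit(pr_tr, y[tr])
        adj <- bias_adjust_apply(pr_te, y[te], bm)
      }
      fold_mses[f] <- mean((adj - y[te])^2)
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, n_test = length(te),
        mse = fold_mses[f],
        hyper = paste(sprintf("%s=%.4g", names(gs$hyper), unlist(gs$hyper)),
                      collapse = ","),
        stringsAsFactors = FALSE)
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, subject = te, target = y[te],
        raw = pr_te, adjusted = adj, stringsAsFactors = FALSE)
    }
    repeat_means[r] <- mean(fold_mses)
  }
  structure(list(
    folds = do.call(rbind, fold_rows),
    predictions = do.call(rbind, pred_rows),
    repeat_means = repeat_means,
    summary = list(mean_mse = mean(repeat_means),
                   sd_mse = stats::sd(repeat_means)),
    mean_abs_weight = stats::setNames(wsum / max(wcount, 1L), colnames(X)),
    family = family, k = k, repeats = repeats, seed = seed,
    bias_adjust = bias_adjust),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold x %d repeats%s: MSE = %.4f +/- %.4f\n",
              x$family, x$k, x$repeats,
              if (x$bias_adjust) " (bias-adjusted)" else "",
              x$summary$mean_mse, x$summary$sd_mse))
  invisible(x)
}
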