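# Regression models, grid search, bias adjustment, repeated CV.

make_reg_problem <- function(n = 40, p = 10, sd = 0.3, seed = 61,
                             beta = c(2, -1.5, rep(0, p - 2))) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  list(X = X, y = drop(X %*% beta) + rnorm(n, 0, sd), beta = beta)
}

test_that("lasso with zero penalty equals OLS; huge penalty collapses to the mean", {
  pr <- make_reg_problem()
  f0 <- fit_model("lasso", pr$X, pr$y, list(lambda = 0))
  ols <- unname(coef(lm(pr$y ~ pr$X)))
  expect_equal(unname(c(f0$intercept, f0$weights)), ols, tolerance = 1e-8)
  fb <- fit_model("lasso", pr$X, pr$y, list(lambda = 1e8))
  expect_true(all(fb$weights == 0))
  expect_equal(fb$intercept, mean(pr$y), tolerance = 1e-10)
  expect_equal(unname(predict(fb, pr$X)), rep(mean(pr$y), 40), tolerance = 1e-10)
})

test_that("elastic net at alpha = 0 coincides with the lasso", {
  pr <- make_reg_problem()
  fe <- fit_model("elastic_net", pr$X, pr$y, list(lambda = 0.4, alpha = 0))
  fl <- fit_model("lasso", pr$X, pr$y, list(lambda = 0.4))
  expect_equal(fe$weights, fl$weights, tolerance = 1e-10)
  expect_equal(fe$intercept, fl$intercept, tolerance = 1e-10)
})

test_that("lasso and elastic-net solutions satisfy their KKT conditions", {
  pr <- make_reg_problem(n = 30, p = 5)
  for (hp in list(list(family = "lasso", lambda = 0.5, alpha = 0),
                  list(family = "lasso", lambda = 2, alpha = 0),
                  list(family = "elastic_net", lambda = 0.5, alpha = 0.3),
                  list(family = "elastic_net", lambda = 0.08, alpha = 0.28))) {
    f <- fit_model(hp$family, pr$X, pr$y,
                   list(lambda = hp$lambda, alpha = hp$alpha))
    expect_lt(kkt_residual(pr$X, pr$y, f$weights, f$intercept,
                           hp$lambda, hp$alpha), 1e-6)
  }
})

test_that("each family's solution beats random perturbations of itself", {
  pr <- make_reg_problem(n = 30, p = 5)
  set.seed(62)
  cases <- list(list(family = "lasso", hyper = list(lambda = 0.5)),
                list(family = "elastic_net", hyper = list(lambda = 0.3, alpha = 0.2)),
                list(family = "svr_linear", hyper = list(C = 1, epsilon = 0.17)))
  for (cs in cases) {
    f <- fit_model(cs$family, pr$X, pr$y, cs$hyper)
    obj0 <- model_objective(cs$family, pr$X, pr$y, f$weights, f$intercept, cs$hyper)
    worse <- replicate(1000, {
      scale <- 10^runif(1, -4, -1)
      w <- f$weights + rnorm(length(f$weights), 0, scale)
      b <- f$intercept + rnorm(1, 0, scale)
      model_objective(cs$family, pr$X, pr$y, w, b, cs$hyper)
    })
    expect_true(all(worse >= obj0 - 1e-7 * max(1, abs(obj0))),
                label = sprintf("%s local optimality", cs$family))
  }
})

test_that("SVR accepts the study's hyperparameters and predicts linearly", {
  pr <- make_reg_problem(n = 50, p = 4, sd = 0.1)
  f <- fit_model("svr_linear", pr$X, pr$y, list(C = 1, epsilon = 0.17))
  expect_length(f$weights, 4)
  expect_gt(cor(predict(f, pr$X), pr$y), 0.95)
  # prediction is exactly the linear form
  expect_equal(predict(f, pr$X),
               drop(pr$X %*% f$weights) + f$intercept)
})

test_that("grid search recovers supports, honors single points and tie-breaks", {
  set.seed(63)
  n <- 50; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- drop(X %*% c(3, -2, rep(0, p - 2)))  # noiseless, 2 active features
  gs <- grid_search("lasso", X, y, seed = 64)
  fit <- fit_model("lasso", X, y, gs$hyper)
  expect_true(all(c(1, 2) %in% which(fit$weights != 0)))

  one <- grid_search("lasso", X, y, grid = data.frame(lambda = 0.25), seed = 64)
  expect_equal(one$hyper$lambda, 0.25)

  # constant targets make every grid point score identically: the smallest
  # hyperparameters must win
  yc <- rep(2, n)
  tie <- grid_search("elastic_net", X, yc,
                     grid = expand.grid(lambda = c(0.1, 0.5), alpha = c(0.2, 0.8)),
                     seed = 65)
  expect_equal(tie$hyper$lambda, 0.1)
  expect_equal(tie$hyper$alpha, 0.2)
})

test_that("bias adjustment inverts affine prediction bias exactly", {
  real <- c(2, 4, 5, 6, 8, 3, 7)
  # unbiased: identity correction
  bm0 <- bias_adjust_fit(real, real)
  expect_equal(bm0$mu, 0); expect_equal(bm0$phi, 0)
  expect_equal(bias_adjust_apply(real, real, bm0), real)
  # constant offset: pred = real + 1
  bm1 <- bias_adjust_fit(real + 1, real)
  expect_equal(bm1$mu, 0, tolerance = 1e-12)
  expect_equal(bm1$phi, 1, tolerance = 1e-12)
  expect_equal(bias_adjust_apply(real + 1, real, bm1), real, tolerance = 1e-12)
  # proportional bias: pred = 1.5 * real
  bm2 <- bias_adjust_fit(1.5 * real, real)
  expect_equal(bm2$mu, 0.5, tolerance = 1e-12)
  expect_equal(bm2$phi, 0, tolerance = 1e-12)
  expect_equal(bias_adjust_apply(1.5 * real, real, bm2), real, tolerance = 1e-12)
  # constant targets are rejected
  expect_error(bias_adjust_fit(c(1, 2), c(3, 3)), "constant")
})

test_that("repeated k-fold CV learns noiseless targets and is deterministic", {
  set.seed(66)
  n <- 40; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- drop(X %*% c(1, 2, 0, 0, -1)) + 5
  cv <- repeated_kfold(X, y, "lasso", k = 5, repeats = 3, seed = 67,
                       grid = data.frame(lambda = c(0.01, 0.1)))
  expect_lt(cv$summary$mean_mse, 1e-3 * var(y))
  cv2 <- repeated_kfold(X, y, "lasso", k = 5, repeats = 3, seed = 67,
                        grid = data.frame(lambda = c(0.01, 0.1)))
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(cv$summary, cv2$summary)
  expect_error(repeated_kfold(X[1:4, ], y[1:4], k = 5), "exceed")
})

test_that("disabling bias adjustment removes all test-target usage", {
  set.seed(68)
  n <- 30; p <- 4
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- drop(X %*% c(1, -1, 0.5, 0)) + rnorm(n, 0, 0.5) + 5
  cv_raw <- repeated_kfold(X, y, "lasso", k = 5, repeats = 2, seed = 69,
                           grid = data.frame(lambda = 0.2), bias_adjust = FALSE)
  # raw predictions are reported unchanged
  expect_equal(cv_raw$predictions$raw, cv_raw$predictions$adjusted)
  cv_adj <- repeated_kfold(X, y, "lasso", k = 5, repeats = 2, seed = 69,
                           grid = data.frame(lambda = 0.2), bias_adjust = TRUE)
  expect_false(isTRUE(all.equal(cv_adj$predictions$adjusted,
                                cv_adj$predictions$raw)))
  # same folds, same raw model outputs: only the adjustment differs
  expect_equal(cv_raw$predictions$raw, cv_adj$predictions$raw)
})
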