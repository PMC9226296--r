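# The temporal grading index estimator and feature assembly.

test_that("tgi_fit solves the deviation regression in closed form", {
  x <- c(1, 2, 3)
  expect_equal(tgi_fit(x, x)[c("k", "b")], list(k = 0, b = 0))
  expect_equal(tgi_fit(x, 2 * x)[c("k", "b")], list(k = 1, b = 0))
  # y - x = (2,3,4) = 1 * x + 1
  expect_equal(tgi_fit(x, c(3, 5, 7))[c("k", "b")], list(k = 1, b = 1))
})

test_that("tgi_fit equals the textbook OLS of y - x on x", {
  set.seed(51)
  for (rep in 1:10) {
    t <- sample(10:200, 1)
    x <- rnorm(t); y <- rnorm(t)
    f <- tgi_fit(x, y)
    ref <- lm((y - x) ~ x)
    expect_equal(f$k, unname(coef(ref)[2]), tolerance = 1e-12)
    expect_equal(f$b, unname(coef(ref)[1]), tolerance = 1e-12)
    expect_equal(f$se_k, summary(ref)$coefficients[2, 2], tolerance = 1e-10)
  }
})

test_that("tgi_fit is affine-equivariant in y and flags flat norms", {
  set.seed(52)
  x <- rnorm(50); y <- 1.3 * x + rnorm(50, 0, 0.2)
  f0 <- tgi_fit(x, y)
  fshift <- tgi_fit(x, y + 2.5)
  expect_equal(fshift$k, f0$k, tolerance = 1e-12)
  expect_equal(fshift$b, f0$b + 2.5, tolerance = 1e-12)
  # adding delta * x to the deviation raises the slope by delta
  fscale <- tgi_fit(x, y + 0.7 * x)
  expect_equal(fscale$k, f0$k + 0.7, tolerance = 1e-12)

  flat <- tgi_fit(rep(1, 50), y)
  expect_false(flat$defined)
  expect_true(is.na(flat$k))
  expect_error(tgi_fit(1:2, 1:2), "3 windows")
})

test_that("slope estimates land within their analytic standard error", {
  set.seed(53)
  t <- 191
  x <- rnorm(t, 1, 0.5)
  y <- 1.4 * x + 0.3 + rnorm(t, 0, 0.05)
  f <- tgi_fit(x, y)
  se <- 0.05 / sqrt(var(x) * (t - 1))
  expect_lt(abs(f$k - 0.4), 3 * se)
  expect_equal(f$b, 0.3, tolerance = 3 * 0.05)  # intercept near truth
})

test_that("tgi_subject recovers injected gradients exactly without noise", {
  x <- make_norm_pm(t = 60, n = 12, seed = 6)
  k_true <- runif(12, -0.5, 0.5); b_true <- rnorm(12, 0, 0.2)
  pats <- simulate_property_matrices(x, k_true, b_true, noise_sd = 0,
                                     n_patients = 2, seed = 3)
  tv <- tgi_subject(pats[[1]], x)
  expect_equal(unname(tv$k), k_true, tolerance = 1e-10)
  expect_equal(unname(tv$b), b_true, tolerance = 1e-10)
  # identical matrices give the zero vector
  z <- tgi_subject(x, x)
  expect_true(all(z$k == 0) && all(z$b == 0))
})

test_that("noisy tier-B recovery matches OLS sampling theory", {
  set.seed(54)
  t <- 120; n <- 60; noise_sd <- 0.1; n_pat <- 10
  x <- make_norm_pm(t = t, n = n, seed = 7)
  k_true <- runif(n, -0.5, 0.5)
  pats <- simulate_property_matrices(x, k_true, rep(0, n), noise_sd,
                                     n_patients = n_pat, seed = 8)
  errs <- c(); ses <- c(); cover <- c()
  for (p in pats) {
    tv <- tgi_subject(p, x)
    errs <- c(errs, tv$k - k_true)
    ses <- c(ses, tv$diagnostics$se_k)
    cover <- c(cover, abs(tv$k - k_true) <= 1.96 * tv$diagnostics$se_k)
  }
  # RMSE within 20% of the analytic prediction noise_sd / sqrt(var(x)*(t-1))
  analytic <- sqrt(mean((noise_sd / sqrt(apply(x$data, 2, var) * (t - 1)))^2))
  expect_lt(abs(sqrt(mean(errs^2)) - analytic) / analytic, 0.2)
  # 95% CI coverage over 600 region-replicates
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("tgi_subject enforces matching shapes and flags flat regions", {
  x <- make_norm_pm(t = 30, n = 5, seed = 9)
  y <- make_norm_pm(t = 30, n = 6, seed = 10)
  expect_error(tgi_subject(y, x), "norm")
  # flat norm column: imputed 0 and flagged
  xf <- x
  xf$data[, 3] <- 1
  pat <- property_matrix(xf$data + 0.1, property = xf$property,
                         subject_id = "p1", labels = xf$labels)
  tv <- tgi_subject(pat, xf)
  expect_equal(unname(tv$k[3]), 0)
  expect_false(tv$diagnostics$defined[3])
  expect_true(all(tv$diagnostics$defined[-3]))
})

test_that("combine_features z-scores per column and orders blocks", {
  mk_tv <- function(k, id, prop) {
    structure(list(k = setNames(k, paste0("R", seq_along(k))),
                   b = setNames(rep(0, length(k)), paste0("R", seq_along(k))),
                   property = prop, subject_id = id,
                   diagnostics = data.frame(defined = rep(TRUE, length(k)))),
              class = "tgi_vector")
  }
  # one feature (1,2,3) -> (-1, 0, 1) under sample-sd scaling
  set1 <- lapply(1:3, function(i) mk_tv(c(i), paste0("s", i), "cc"))
  Z <- combine_features(list(cc = set1))
  expect_equal(unname(Z[, 1]), c(-1, 0, 1))
  # constant column -> zeros with warning
  setc <- lapply(1:3, function(i) mk_tv(c(5), paste0("s", i), "cc"))
  expect_warning(Zc <- combine_features(list(cc = setc)), "zero-variance")
  expect_true(all(Zc == 0))
  # 3 properties x 10 regions x 20 subjects -> 20 x 30, block-ordered names
  set.seed(55)
  sets <- lapply(c("degree", "cc", "pc"), function(p)
    lapply(1:20, function(i) mk_tv(rnorm(10), sprintf("s%02d", i), p)))
  names(sets) <- c("degree", "cc", "pc")
  Z3 <- combine_features(sets)
  expect_identical(dim(Z3), c(20L, 30L))
  expect_identical(colnames(Z3)[1], "degree:R1")
  expect_identical(colnames(Z3)[11], "cc:R1")
  expect_identical(colnames(Z3)[30], "pc:R10")
  expect_true(all(abs(colMeans(Z3)) < 1e-12))
  expect_true(all(abs(apply(Z3, 2, sd) - 1) < 1e-12))
})

test_that("standardization fitted on training rows does not use held-out rows", {
  set.seed(56)
  X <- matrix(rnorm(200), 20, 10)
  train <- 1:12
  Z <- standardize_features(X, rows = train)
  # training block is standardized...
  expect_true(all(abs(colMeans(Z[train, ])) < 1e-12))
  # ...the held-out block is generally not (no leakage of its statistics)
  expect_gt(max(abs(colMeans(Z[-train, ]))), 1e-6)
  # and the recorded parameters come from the training rows alone
  expect_equal(attr(Z, "center"), colMeans(X[train, ]))
})
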