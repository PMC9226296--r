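# Synthetic-cohort generators: partitions, tier-A time series, tier-B
# property matrices, VAS coupling, motion traces.

test_that("make_partition assigns contiguous blocks and validates sizes", {
  p <- make_partition(10, c(4, 6))
  expect_identical(p$module, c(rep("M1", 4), rep("M2", 6)))
  expect_identical(length(p), 10L)
  expect_s3_class(make_partition(4, 4), "module_partition")  # single module ok
  expect_error(make_partition(4, c(2, 3)), "sum to 5")
})

test_that("default partition matches the atlas's modular structure", {
  p <- default_partition()
  expect_identical(length(p), 274L)
  expect_identical(length(p$modules), 9L)
  expect_identical(sum(p$module == "cerebellar"), 28L)
  expect_identical(sum(p$module == "subcortical"), 32L)
  # subcortical set: amygdala, basal ganglia, thalamus label ranges
  sub_idx <- which(p$module == "subcortical")
  expect_identical(sub_idx, c(211:214, 219:230, 231:246))
  expect_identical(which(p$module == "cerebellar"), 247:274)
  # seven cortical systems cover the rest
  expect_identical(sum(!p$module %in% c("subcortical", "cerebellar")), 214L)
})

test_that("tier-A cohorts are seed-deterministic and correctly shaped", {
  a <- simulate_cohort_timeseries(n_hc = 2, n_cbp = 2, n_regions = 20, T = 60,
                                  tr = 2.5, n_states = 3, dwell_mean = 30,
                                  cbp_shift = 0.3, seed = 7)
  b <- simulate_cohort_timeseries(n_hc = 2, n_cbp = 2, n_regions = 20, T = 60,
                                  tr = 2.5, n_states = 3, dwell_mean = 30,
                                  cbp_shift = 0.3, seed = 7)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$meta, b$meta)
  expect_identical(dim(a$subjects[[1]]$data), c(60L, 20L))
  expect_identical(a$meta$group, c("HC", "HC", "CBP", "CBP"))
  # VAS present iff patient
  expect_true(all(is.na(a$meta$vas[a$meta$group == "HC"])))
  expect_true(all(!is.na(a$meta$vas[a$meta$group == "CBP"])))
  c_ <- simulate_cohort_timeseries(n_hc = 2, n_cbp = 2, n_regions = 20, T = 60,
                                   tr = 2.5, n_states = 3, dwell_mean = 30,
                                   cbp_shift = 0.3, seed = 8)
  expect_false(identical(a$subjects[[1]]$data, c_$subjects[[1]]$data))
})

test_that("null cohorts (cbp_shift = 0) give nominal two-sample rejection rates", {
  # Monte-Carlo calibration: group labels carry no signal, so a two-sample
  # t-test on a windowed network summary should reject at about alpha.
  n_seeds <- 200
  alpha <- 0.05
  pvals <- vapply(seq_len(n_seeds), function(s) {
    co <- simulate_cohort_timeseries(n_hc = 4, n_cbp = 4, n_regions = 10,
                                     T = 50, tr = 2.5, n_states = 2,
                                     dwell_mean = 15, cbp_shift = 0, seed = s)
    spec <- suppressWarnings(sliding_window_indices(50, 20, 5, tr = 2.5))
    stat <- vapply(co$subjects, function(ts) {
      st <- build_dfc_stack(ts, spec)
      mean(dynamic_property_matrix(st, "degree", degree_mode = "strength")$data)
    }, numeric(1))
    stats::t.test(stat[co$meta$group == "HC"],
                  stat[co$meta$group == "CBP"], var.equal = TRUE)$p.value
  }, numeric(1))
  rate <- mean(pvals < alpha)
  # binomial(200, 0.05) 99.9% interval is roughly [0.005, 0.115]
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.12)
})

test_that("shifted cohorts separate in windowed CC and PC (frozen regression)", {
  # The covariance shift (within-module boost, between-module damping) must
  # surface as group differences in windowed clustering and participation.
  # Power at these conditions was checked once by Monte-Carlo (1.0 over 30
  # replicates for both metrics); this fixed-seed case guards the effect.
  co <- simulate_cohort_timeseries(n_hc = 15, n_cbp = 15, n_regions = 20,
                                   T = 100, tr = 2.5, n_states = 3,
                                   dwell_mean = 25, cbp_shift = 0.5, seed = 1)
  spec <- suppressWarnings(sliding_window_indices(100, 40, 10, tr = 2.5))
  mats <- lapply(co$subjects, build_dfc_stack, spec = spec)
  g <- co$meta$group
  for (prop in c("cc", "pc")) {
    m <- vapply(mats, function(st)
      mean(dynamic_property_matrix(st, prop, co$partition)$data), numeric(1))
    p <- t.test(m[g == "HC"], m[g == "CBP"], var.equal = TRUE)$p.value
    expect_lt(p, 0.05)
  }
})

test_that("stationary cohorts fluctuate less with longer windows", {
  co <- simulate_cohort_timeseries(n_hc = 1, n_cbp = 0, n_regions = 6,
                                   T = 240, tr = 2.5, n_states = 1,
                                   dwell_mean = 30, seed = 3)
  ts <- co$subjects[[1]]
  var_fc <- function(L) {
    spec <- suppressWarnings(sliding_window_indices(240, L, 5, tr = 2.5))
    st <- build_dfc_stack(ts, spec)
    edge <- st$arr[, 1, 2]
    stats::var(edge)
  }
  expect_lt(var_fc(100), var_fc(30))
})

test_that("tier-B generator realizes the deviation-gradient model exactly", {
  x <- make_norm_pm(t = 40, n = 8, seed = 2)
  # zero gradient, zero noise: identity
  y0 <- simulate_property_matrices(x, k_true = rep(0, 8), b_true = rep(0, 8),
                                   noise_sd = 0, n_patients = 2, seed = 1)
  expect_equal(y0[[1]]$data, x$data, tolerance = 1e-15, ignore_attr = TRUE)
  # unit slope doubles the norm course
  y1 <- simulate_property_matrices(x, k_true = rep(1, 8), b_true = rep(0, 8),
                                   noise_sd = 0, n_patients = 1, seed = 1)
  expect_equal(y1[[1]]$data, 2 * x$data, tolerance = 1e-15, ignore_attr = TRUE)
  # determinism and ground-truth bookkeeping
  y2 <- simulate_property_matrices(x, k_true = runif(8), b_true = rnorm(8),
                                   noise_sd = 0.1, n_patients = 3, seed = 9)
  y3 <- simulate_property_matrices(x, k_true = attr(y2[[1]], "k_true"),
                                   b_true = attr(y2[[1]], "b_true"),
                                   noise_sd = 0.1, n_patients = 3, seed = 9)
  expect_identical(lapply(y2, `[[`, "data"), lapply(y3, `[[`, "data"))
})

test_that("simulate_vas couples targets to features and clips to scale", {
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(simulate_vas(X, rep(0, 4), intercept = 3.5, noise_sd = 0, seed = 1),
               rep(3.5, 10))
  v <- simulate_vas(X, c(0.4, 0, 0, 0), intercept = 5, noise_sd = 0, seed = 1)
  expect_equal(unname(cor(v, X[, 1])), 1, tolerance = 1e-12)
  expect_warning(simulate_vas(X, c(50, 0, 0, 0), intercept = 5,
                              noise_sd = 0, seed = 1), "clipped")
  v2 <- suppressWarnings(simulate_vas(X, c(50, 0, 0, 0), 5, 0, 1))
  expect_true(all(v2 >= 0 & v2 <= 10))
  expect_error(simulate_vas(X, rep(0, 3)), "length")
})

test_that("motion traces drive the QC rule as designed", {
  # no noise, no spikes: all zero, included
  m0 <- simulate_motion_trace(50, base_sd = 0, n_spikes = 0, seed = 1)
  expect_true(all(m0 == 0))
  expect_true(motion_qc(m0)$include)
  # one 3 mm spike on a translation axis excludes
  m1 <- simulate_motion_trace(50, base_sd = 0, n_spikes = 1, spike_amp = 3,
                              seed = 2)
  d1 <- motion_qc(m1)
  expect_false(d1$include)
  expect_true("translation" %in% d1$reasons)
  # increment sd chosen for mean FD ~ 0.29 (about 4.8 * base_sd) excludes
  m2 <- simulate_motion_trace(240, base_sd = 0.06, n_spikes = 0, seed = 3)
  d2 <- motion_qc(m2)
  expect_false(d2$include)
  expect_true("fd" %in% d2$reasons)
  expect_gt(d2$mean_fd, 0.2)
})
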