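# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own vectorized
# code paths: metrics are computed by explicit loops, regressions by
# textbook closed forms.

# --- graph-metric oracles (explicit loops over node pairs/triples) -------

bf_degree_count <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) sum(w[i, -i] > 0))
}

bf_degree_strength <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) sum(w[i, -i]))
}

bf_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, -i] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

bf_participation <- function(w, modules) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- sum(w[i, -i])
    if (s == 0) next
    acc <- 0
    for (m in unique(modules)) {
      sm <- sum(w[i, setdiff(which(modules == m), i)])
      acc <- acc + (sm / s)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# All undirected binary graphs on n nodes, as adjacency matrices.
enumerate_graphs <- function(n) {
  n_edges <- n * (n - 1) / 2
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lapply(seq_len(2^n_edges) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_edges)]
    w <- matrix(0, n, n)
    w[idx] <- bits
    w + t(w)
  })
}

random_weighted_graph <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) > density] <- 0
  w[up] <- vals
  w + t(w)
}

# --- regression oracles --------------------------------------------------

# Penalized objective the fitted models are supposed to minimize (squared
# error on the per-sample scale for lasso / elastic net).
model_objective <- function(family, X, y, w, b, hyper) {
  r <- y - drop(as.matrix(X) %*% w) - b
  n <- length(y)
  switch(family,
         lasso = sum(r^2) / (2 * n) + hyper$lambda * sum(abs(w)),
         elastic_net = sum(r^2) / (2 * n) + hyper$lambda * sum(abs(w)) +
           hyper$alpha * sum(w^2),
         svr_linear = {
           eps <- hyper$epsilon; C <- hyper$C
           0.5 * sum(w^2) + C * sum(pmax(abs(r) - eps, 0))
         })
}

# Subgradient (KKT) residual for lasso / elastic net.
kkt_residual <- function(X, y, w, b, lambda, alpha = 0) {
  n <- length(y)
  r <- y - drop(as.matrix(X) %*% w) - b
  g <- -drop(crossprod(as.matrix(X), r)) / n + 2 * alpha * w
  resid <- ifelse(w != 0, abs(g + lambda * sign(w)), pmax(abs(g) - lambda, 0))
  max(c(resid, abs(mean(r))))
}

# --- fixtures ------------------------------------------------------------

make_test_ts <- function(T = 60, n = 6, tr = 2.5, seed = 1,
                         subject_id = "test") {
  set.seed(seed)
  roi_ts(matrix(rnorm(T * n), T, n), tr = tr, subject_id = subject_id)
}

# A smooth norm property series with per-region variance, t windows.
make_norm_pm <- function(t = 100, n = 20, seed = 1, property = "cc") {
  set.seed(seed)
  base <- outer(sin(seq(0, 4 * pi, length.out = t)), runif(n, 0.5, 1.5))
  x <- 0.5 + 0.2 * base + matrix(rnorm(t * n, 0, 0.05), t, n)
  property_matrix(x, property = property, subject_id = "HC_mean")
}
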