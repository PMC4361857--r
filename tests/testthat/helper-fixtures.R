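# Shared fixtures, built in code.

# Minimal well-formed specimen table with all QC fields interior to the
# acceptance region.
make_specimens <- function(n = 5, region = "western", year = 2000) {
  pct_C <- rep(43, n); cn <- rep(3.2, n)
  pct_N <- pct_C * (14.007 / 12.011) / cn
  cs <- rep(500, n)
  pct_S <- pct_C * (32.06 / 12.011) / cs
  df <- data.frame(
    specimen_id = sprintf("sp%02d", seq_len(n)), region = region,
    site = "s", year_lo = year, year_hi = year, age_class = "adult",
    age_years = 8, d13C = rnorm(n, -20, 0.5), d15N = rnorm(n, 8, 0.5),
    d34S = rnorm(n, 6, 0.5), pct_C = pct_C, pct_N = pct_N, pct_S = pct_S)
  cbind(df, atomic_ratios(pct_C, pct_N, pct_S))
}

# Two-cluster source samples for KNN tests.
make_clusters <- function(n = 10, gap = 100, sd = 1, seed = 1, d = 2) {
  set.seed(seed)
  list(a = matrix(rnorm(n * d, 0, sd), n),
       b = matrix(rnorm(n * d, gap, sd), n))
}

# Independent brute-force oracle for the KNN statistic and its exhaustive
# permutation p-value; deliberately naive, shares no code with the package.
oracle_knn_stat <- function(X, labels, k) {
  n <- nrow(X)
  fr <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(X) - X[i, ])^2)
    d2[i] <- Inf
    nn <- order(d2, seq_len(n))[seq_len(k)]
    fr[i] <- mean(labels[nn] == labels[i])
  }
  mean(fr)
}

oracle_knn_exact_p <- function(X, na, k) {
  n <- nrow(X)
  labs0 <- rep(c(1, 2), c(na, n - na))
  obs <- oracle_knn_stat(X, labs0, k)
  combs <- utils::combn(n, na)
  stats <- apply(combs, 2, function(ix) {
    lab <- rep(2, n); lab[ix] <- 1
    oracle_knn_stat(X, lab, k)
  })
  mean(stats >= obs - 1e-12)
}

# Three-source scenario with well-separated channels, for decisive
# recovery tests (K = 3 is fully identified with 3 channels).
three_source_scenario <- function(p = c(A = 0.6, B = 0.3, C = 0.1),
                                  n_consumers = 30, seed = 1) {
  src <- data.frame(
    category = c("A", "B", "C"),
    d13C = c(-28, -20, -12), d15N = c(1, 8, 15), d34S = c(0, 8, 16),
    omega = 0.8, pct_C = c(45, 45, 45), pct_N = c(3, 10, 12),
    pct_S = c(0.3, 0.7, 1.0), n = 15)
  scenario(region = "eastern", sources = src,
           true_p = list(period3 = p), n_consumers = n_consumers,
           seed = seed)
}
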