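test_that("complete separation gives stat 1 and the minimal p-value", {
  cl <- make_clusters(n = 10, gap = 100, sd = 1, seed = 2)
  res <- knn_randomization_test(cl$a, cl$b, k = 3, n_perm = 99, seed = 1)
  expect_equal(res$observed_stat, 1.0)
  expect_equal(res$p_value, 1 / 100)
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
})

test_that("statistic and exact p match an independent brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(12), 6, 2)
    a <- X[1:3, , drop = FALSE]; b <- X[4:6, , drop = FALSE]
    res <- knn_randomization_test(a, b, k = 1, exact = TRUE)
    expect_equal(res$observed_stat, oracle_knn_stat(X, rep(1:2, each = 3), 1))
    expect_equal(res$p_value, oracle_knn_exact_p(X, 3, 1))
    expect_equal(res$n_permutations, choose(6, 3))
  }
})

test_that("Monte-Carlo p converges to the enumeration p", {
  set.seed(33)
  X <- matrix(rnorm(16), 8, 2)
  a <- X[1:4, , drop = FALSE]; b <- X[5:8, , drop = FALSE]
  p_exact <- knn_randomization_test(a, b, k = 3, exact = TRUE)$p_value
  p_mc <- knn_randomization_test(a, b, k = 3, n_perm = 20000,
                                 seed = 4)$p_value
  expect_lt(abs(p_mc - p_exact), 0.02)
})

test_that("identical groups are not declared different", {
  # group b an exact interleaved copy of group a: null is true by design
  set.seed(5)
  a <- matrix(rnorm(20), 10, 2)
  over <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    res <- knn_randomization_test(a, a + 1e-9, k = 3, n_perm = 199,
                                  seed = s)
    if (res$p_value > 0.05) over <- over + 1L
    if (s == 1) expect_true(TRUE)
  }
  expect_gte(over / n_seeds, 0.95)
})

test_that("results are deterministic given a seed and flag degeneracy", {
  cl <- make_clusters(n = 5, gap = 3, sd = 1, seed = 7)
  r1 <- knn_randomization_test(cl$a, cl$b, k = 2, n_perm = 199, seed = 11)
  r2 <- knn_randomization_test(cl$a, cl$b, k = 2, n_perm = 199, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  same <- matrix(1, 4, 2)
  res <- knn_randomization_test(same, same, k = 2, n_perm = 49, seed = 1)
  expect_true(res$degenerate)
})

test_that("pairwise tests derive the Bonferroni threshold from pair count", {
  sc <- study_scenario(seed = 3)
  src <- generate_sources(sc)
  pw <- pairwise_source_tests(src, k = 3, n_perm = 999, seed = 1)
  expect_equal(pw$m, 10)
  expect_equal(pw$alpha_adjusted, 0.005)   # 0.05 / C(5,2)
  expect_true(all(pw$p_matrix[upper.tri(pw$p_matrix)] <= 1))
  # 2 categories -> single comparison, threshold stays at the family level
  two <- src[src$category %in% c("salmon", "corn"), ]
  pw2 <- pairwise_source_tests(two, k = 3, n_perm = 99, seed = 1)
  expect_equal(pw2$alpha_adjusted, 0.05)
  # 6 categories -> 15 pairs
  extra <- src[src$category == "salmon", ]
  extra$category <- "extra"; extra$d15N <- extra$d15N + 30
  pw6 <- pairwise_source_tests(rbind(src, extra), k = 3, n_perm = 999,
                               seed = 1)
  expect_equal(pw6$m, 15)
  expect_equal(pw6$alpha_adjusted, 0.05 / 15, tolerance = 1e-12)
})

test_that("type-I error of the KNN test is calibrated at alpha = 0.05", {
  # identical generating distribution in both groups; 500 datasets
  n_data <- 500
  rej <- 0L
  for (s in seq_len(n_data)) {
    set.seed(s + 40000)
    a <- matrix(rnorm(20), 10, 2)
    b <- matrix(rnorm(20), 10, 2)
    p <- knn_randomization_test(a, b, k = 3, n_perm = 199,
                                seed = s)$p_value
    if (p <= 0.05) rej <- rej + 1L
  }
  rate <- rej / n_data
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_data)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("pooling is the transitive closure of non-significant pairs", {
  pm <- matrix(c(NA, 0.2, 0.001,
                 0.2, NA, 0.2,
                 0.001, 0.2, NA), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  samples <- data.frame(
    sample_id = 1:12, category = rep(c("A", "B", "C"), each = 4),
    region = "western", d13C = rnorm(12, -25), d15N = rnorm(12, 3),
    d34S = rnorm(12, 5), pct_C = 45, pct_N = 3, pct_S = 0.3)
  # A~B and B~C non-significant, A~C significant: all three pooled, flagged
  part <- merge_sources(list(p_matrix = pm, alpha_adjusted = 0.05), samples)
  expect_equal(unique(part$mapping$group), "A+B+C")
  expect_true(part$merged_significant_pair)
  # all pairs significant: partition unchanged
  pm2 <- pm; pm2[] <- 0.001; diag(pm2) <- NA
  part2 <- merge_sources(list(p_matrix = pm2, alpha_adjusted = 0.05),
                         samples)
  expect_equal(part2$mapping$group, part2$mapping$category)
  expect_false(part2$merged_significant_pair)
  # one non-significant pair pools exactly that pair
  pm3 <- pm2; pm3["A", "B"] <- pm3["B", "A"] <- 0.2
  part3 <- merge_sources(list(p_matrix = pm3, alpha_adjusted = 0.05),
                         samples)
  expect_setequal(unique(part3$mapping$group), c("A+B", "C"))
})

test_that("pooled group mean is the sample-size-weighted member mean", {
  set.seed(13)
  samples <- data.frame(
    sample_id = 1:7, category = rep(c("A", "B"), c(3, 4)),
    region = "western", d13C = rnorm(7, -25), d15N = rnorm(7, 3),
    d34S = rnorm(7, 5), pct_C = 45, pct_N = 3, pct_S = 0.3)
  pm <- matrix(c(NA, 0.5, 0.5, NA), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  part <- merge_sources(list(p_matrix = pm, alpha_adjusted = 0.05), samples)
  w <- (3 * mean(samples$d13C[1:3]) + 4 * mean(samples$d13C[4:7])) / 7
  expect_equal(unname(part$groups$mu["A+B", "d13C"]), w, tolerance = 1e-12)
})
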