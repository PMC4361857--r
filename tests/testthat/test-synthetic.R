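test_that("scenario construction validates its inputs", {
  sc <- study_scenario()
  expect_s3_class(sc, "iso_scenario")
  for (p in sc$true_p) expect_equal(sum(p), 1, tolerance = 1e-12)
  # period 1 has no corn on offer
  expect_false("corn" %in% names(sc$true_p$period1))
  bad <- sc$sources
  expect_error(scenario(sources = bad,
                        true_p = list(period1 = c(C3_herb = 0.6,
                                                  salmon = 0.3))),
               "sum to 1")
})

test_that("source generation is deterministic and centred on the truth", {
  sc <- study_scenario(seed = 6)
  s1 <- generate_sources(sc)
  s2 <- generate_sources(sc)
  expect_identical(s1, s2)            # bit-identical reruns
  # zero spread collapses samples onto the category means
  sc0 <- sc; sc0$sources$omega <- 0
  s0 <- generate_sources(sc0)
  expect_equal(s0$d13C[s0$category == "salmon"],
               rep(-16, sum(s0$category == "salmon")))
  # CLT: sample means approach the definitions at n = 200
  scbig <- sc; scbig$sources$n <- 200
  sbig <- generate_sources(scbig, seed = 8)
  for (cat in scbig$sources$category) {
    mu <- scbig$sources$d15N[scbig$sources$category == cat]
    xm <- mean(sbig$d15N[sbig$category == cat])
    expect_lt(abs(xm - mu), 3 * 0.8 / sqrt(200))
  }
})

test_that("consumer generation follows the forward mixing model", {
  sc <- study_scenario(n_consumers = 12, seed = 10)
  # degenerate limit: one source, all variances zero, no drift
  scd <- sc
  scd$sources$omega <- 0
  scd$sigma[] <- 0; scd$meas_error[] <- 0
  scd$tdf <- discrimination_factors(tau = c(d13C = 0, d15N = 0, d34S = 0))
  scd$true_p <- list(period3 = c(salmon = 1))
  cons <- generate_consumers(scd, "period3")
  expect_equal(cons$d13C, rep(-16 + 5, 12), tolerance = 1e-12)
  expect_equal(cons$d15N, rep(14 + 3, 12), tolerance = 1e-12)
  expect_equal(cons$d34S, rep(16 + 1, 12), tolerance = 1e-12)
  # period 3 carries no temporal drift under the default offsets
  expect_equal(suess_offset("period3", sc$correction), 0)
})

test_that("historical periods carry the configured carbon drift", {
  sc <- study_scenario(n_consumers = 400, seed = 12)
  sc$sigma[] <- 0.01; sc$meas_error[] <- 0.01
  sc$true_p$period3 <- sc$true_p$period1   # same diet, different period
  c1 <- generate_consumers(sc, "period1", seed = 1)
  c3 <- generate_consumers(sc, "period3", seed = 1)
  drift <- mean(c1$d13C) - mean(c3$d13C)
  sd_atom <- sqrt(2.9)  # dominated by TDF spread
  expect_lt(abs(drift - 1.6), 3 * sd_atom * sqrt(2 / 400))
})

test_that("contamination and young-animal bookkeeping is exact", {
  sc <- study_scenario(n_consumers = 50, contamination_rate = 0.2,
                           young_rate = 0.1, seed = 14)
  cons <- generate_consumers(sc, "period2")
  truth <- attr(cons, "truth")$table
  expect_equal(nrow(cons), 55)
  expect_equal(sum(truth$degraded), 10)     # floor(0.2 * 50)
  expect_equal(sum(truth$young), 5)
  cn <- cons$CN[truth$degraded]
  expect_true(all(cn < 2.9 | cn > 3.6))
  expect_true(all(cons$CN[!truth$degraded] >= 2.9 &
                    cons$CN[!truth$degraded] <= 3.6))
  expect_true(all(cons$age_years[truth$young] <= 2))
})

test_that("generator and likelihood are mutually consistent", {
  # average log-likelihood at the true proportions beats perturbed ones
  sc <- three_source_scenario(p = c(A = 0.5, B = 0.3, C = 0.2),
                              n_consumers = 400, seed = 16)
  src <- source_groups(generate_sources(sc))
  cons <- generate_consumers(sc, "period3")
  truth <- sc$true_p$period3
  sig <- sqrt(sc$sigma^2 + sc$meas_error^2)[c("d13C", "d15N", "d34S")]
  ll <- function(p) log_posterior(p, sig, cons, src, sc$tdf)
  l0 <- ll(truth)
  for (d in list(c(0.2, -0.2, 0), c(-0.2, 0, 0.2), c(0, 0.2, -0.2))) {
    p <- truth + d
    if (all(p > 0)) expect_gt(l0, ll(p / sum(p)))
  }
})

test_that("the packaged scenario recovers the salmon decline ordering", {
  # Period 1 salmon consumption exceeds Period 3 in the posterior mean
  ok <- 0L
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    sc <- study_scenario(n_consumers = 20, seed = 100 + s)
    src <- source_groups(generate_sources(sc))
    src1 <- isodiet:::subset_source_groups(src, setdiff(src$names, "corn"))
    fits <- lapply(c(period1 = "period1", period3 = "period3"), function(per) {
      cons <- generate_consumers(sc, per)
      corr <- correct_sources_for_period(
        if (per == "period1") src1 else src, per, sc$correction)
      fit_mixing_model(cons, corr, config = mixing_config(
        n_iter = 15000, burn_in = 3000, seed = s))
    })
    if (coef(fits$period1)["salmon"] > coef(fits$period3)["salmon"])
      ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.95)
})
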