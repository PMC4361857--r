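make_groups <- function(mu, omega, q, channels = colnames(mu)) {
  cats <- rownames(mu)
  structure(list(names = cats, channels = channels,
                 mu = mu, omega = omega, q = q,
                 n = setNames(rep(10L, length(cats)), cats)),
            class = "source_groups")
}

two_source_one_channel <- function(q1 = 0.4, q2 = 0.1) {
  mu <- matrix(c(-28, -12), 2, 1, dimnames = list(c("s1", "s2"), "d13C"))
  make_groups(mu, omega = mu * 0, q = matrix(c(q1, q2), 2, 1,
              dimnames = dimnames(mu)))
}

test_that("equal concentrations reduce to the plain (unweighted) model", {
  set.seed(41)
  mu <- matrix(rnorm(6, -20, 5), 3, 2,
               dimnames = list(c("a", "b", "c"), c("d13C", "d15N")))
  omega <- matrix(0.8, 3, 2, dimnames = dimnames(mu))
  q <- matrix(0.3, 3, 2, dimnames = dimnames(mu))
  g <- make_groups(mu, omega, q)
  tdf <- discrimination_factors(c(d13C = 5, d15N = 3), c(d13C = 1.5,
                                                         d15N = 1.5))
  X <- matrix(rnorm(10, -15, 2), 5, 2,
              dimnames = list(NULL, c("d13C", "d15N")))
  p <- c(0.5, 0.3, 0.2); sigma <- c(0.7, 0.9)
  lp <- log_posterior(p, sigma, X, g, tdf, alpha = 1, sigma_upper = 20)
  # independent plain-model computation: p' = p exactly
  mean_j <- colSums(p * (mu + rep(c(5, 3), each = 3)))
  var_j <- colSums(p^2 * (omega^2 + rep(c(1.5, 1.5)^2, each = 3))) + sigma^2
  ll <- sum(vapply(1:2, function(j)
    sum(dnorm(X[, j], mean_j[j], sqrt(var_j[j]), log = TRUE)), numeric(1)))
  expect_equal(lp, ll, tolerance = 1e-10)
})

test_that("a single source predicts mean mu + lambda on every channel", {
  mu <- matrix(c(-25, 4), 1, 2, dimnames = list("only", c("d13C", "d15N")))
  g <- make_groups(mu, omega = mu * 0,
                   q = matrix(0.4, 1, 2, dimnames = dimnames(mu)))
  tdf <- discrimination_factors(c(d13C = 5, d15N = 3),
                                c(d13C = 0, d15N = 0))
  at_pred <- matrix(c(-20, 7), 1, 2,
                    dimnames = list(NULL, c("d13C", "d15N")))
  lp0 <- log_posterior(1, c(0.5, 0.5), at_pred, g, tdf)
  lp1 <- log_posterior(1, c(0.5, 0.5), at_pred + 0.5, g, tdf)
  expect_equal(lp0, sum(dnorm(0, 0, 0.5, log = TRUE) * 2), tolerance = 1e-10)
  expect_gt(lp0, lp1)
})

test_that("zero-variance two-source model is maximised at the algebraic mix", {
  g <- two_source_one_channel(q1 = 0.4, q2 = 0.1)
  tdf <- discrimination_factors(c(d13C = 5), c(d13C = 0))
  p_true <- 0.35
  # concentration-weighted mean at p_true
  M <- g$mu[, 1] + 5
  w <- p_true * 0.4 / (p_true * 0.4 + (1 - p_true) * 0.1)
  xbar <- w * M[1] + (1 - w) * M[2]
  X <- matrix(xbar, 1, 1, dimnames = list(NULL, "d13C"))
  grid <- seq(1e-4, 1 - 1e-4, length.out = 10000)
  ll <- vapply(grid, function(p)
    log_posterior(c(p, 1 - p), 0.05, X, g, tdf), numeric(1))
  p_hat <- grid[which.max(ll)]
  # independent algebraic inversion: w = (xbar - M2)/(M1 - M2), then
  # unweight the concentrations
  w_inv <- unname((xbar - M[2]) / (M[1] - M[2]))
  p_alg <- (w_inv / 0.4) / (w_inv / 0.4 + (1 - w_inv) / 0.1)
  expect_equal(p_alg, p_true, tolerance = 1e-10)
  expect_lt(abs(p_hat - p_alg), 1e-3)
})

test_that("log_posterior guards its support and channel agreement", {
  g <- two_source_one_channel()
  X <- matrix(-20, 1, 1, dimnames = list(NULL, "d13C"))
  expect_equal(log_posterior(c(1, 0), 0.5, X, g), -Inf)
  expect_equal(log_posterior(c(0.5, 0.5), -1, X, g), -Inf)
  expect_equal(log_posterior(c(0.5, 0.5), 30, X, g), -Inf)
  expect_error(log_posterior(c(0.5, 0.5), 0.5,
                             matrix(8, 1, 1, dimnames = list(NULL, "d15N")),
                             g), "channel")
  expect_error(log_posterior(c(0.7, 0.2), 0.5, X, g), "sum to 1")
})

test_that("every stored draw lies on the simplex to 1e-12", {
  sc <- three_source_scenario(seed = 2)
  src <- source_groups(generate_sources(sc))
  cons <- generate_consumers(sc, "period3")
  fit <- fit_mixing_model(cons, src, config = mixing_config(
    n_iter = 5000, burn_in = 1000, seed = 3))
  p <- fit$draws[, fit$sources$names, drop = FALSE]
  expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
  expect_true(all(p > 0))
  sig <- fit$draws[, paste0("sigma_", fit$channels)]
  expect_true(all(sig > 0 & sig <= 20))
})

test_that("with no consumers the sampler reproduces the Dirichlet prior", {
  mu <- matrix(rnorm(8), 4, 2,
               dimnames = list(letters[1:4], c("d13C", "d15N")))
  g <- make_groups(mu, omega = abs(mu) * 0 + 0.5,
                   q = matrix(0.4, 4, 2, dimnames = dimnames(mu)))
  cons <- data.frame(d13C = numeric(), d15N = numeric())
  tdf <- discrimination_factors(c(d13C = 5, d15N = 3),
                                c(d13C = 1.5, d15N = 1.5))
  fit <- fit_mixing_model(cons, g, tdf, mixing_config(
    n_iter = 60000, burn_in = 10000, seed = 7))
  means <- coef(fit)
  # Dirichlet(1) prior mean is 1/K; MC error with ESS in the hundreds
  expect_true(all(abs(means - 0.25) < 0.03))
  vars <- apply(fit$draws[, 1:4], 2, var)
  expect_true(all(abs(vars - 0.25 * 0.75 / 5) < 0.01))
})

test_that("three well-separated sources are recovered within 0.07", {
  # seed-averaged over 5 seeds at the module's reference proportions
  errs <- sapply(1:5, function(s) {
    sc <- three_source_scenario(p = c(A = 0.6, B = 0.3, C = 0.1), seed = s)
    src <- source_groups(generate_sources(sc))
    cons <- generate_consumers(sc, "period3")
    fit <- fit_mixing_model(cons, src, config = mixing_config(
      n_iter = 30000, burn_in = 6000, seed = s))
    est <- coef(fit)
    max(abs(est - sc$true_p$period3[names(est)]))
  })
  expect_lt(mean(errs), 0.07)
})

test_that("relabelling the sources permutes the posterior", {
  sc <- three_source_scenario(seed = 11)
  src <- source_groups(generate_sources(sc))
  cons <- generate_consumers(sc, "period3")
  cfg <- mixing_config(n_iter = 30000, burn_in = 6000, seed = 5)
  fit1 <- fit_mixing_model(cons, src, config = cfg)
  perm <- c(3, 1, 2)
  src2 <- structure(list(names = src$names[perm], channels = src$channels,
                         mu = src$mu[perm, ], omega = src$omega[perm, ],
                         q = src$q[perm, ], n = src$n[perm]),
                    class = "source_groups")
  fit2 <- fit_mixing_model(cons, src2, config = cfg)
  m1 <- coef(fit1); m2 <- coef(fit2)
  expect_equal(m2[names(m1)], m1, tolerance = 0.03)
})

test_that("doubling the chain length moves means by < 2 MC errors", {
  sc <- three_source_scenario(seed = 19)
  src <- source_groups(generate_sources(sc))
  cons <- generate_consumers(sc, "period3")
  f1 <- fit_mixing_model(cons, src, config = mixing_config(
    n_iter = 20000, burn_in = 5000, seed = 1))
  f2 <- fit_mixing_model(cons, src, config = mixing_config(
    n_iter = 40000, burn_in = 5000, seed = 2))
  for (g in src$names) {
    se1 <- sd(f1$draws[, g]) / sqrt(f1$ess[g])
    se2 <- sd(f2$draws[, g]) / sqrt(f2$ess[g])
    expect_lt(abs(coef(f1)[g] - coef(f2)[g]), 2 * sqrt(se1^2 + se2^2) + 0.01)
  }
})

test_that("fits are deterministic given the seed", {
  sc <- three_source_scenario(seed = 23)
  src <- source_groups(generate_sources(sc))
  cons <- generate_consumers(sc, "period3")
  cfg <- mixing_config(n_iter = 3000, burn_in = 500, seed = 9)
  f1 <- fit_mixing_model(cons, src, config = cfg)
  f2 <- fit_mixing_model(cons, src, config = cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("posterior_mode finds modes, not averages", {
  expect_equal(as.numeric(posterior_mode(rep(0.5, 100))), 0.5)
  set.seed(47)
  beta_draws <- rbeta(1e5, 2, 5)
  expect_lt(abs(as.numeric(posterior_mode(beta_draws)) - 0.2), 0.02)
  bimodal <- c(rnorm(3000, 0.2, 0.03), rnorm(7000, 0.8, 0.03))
  expect_lt(abs(as.numeric(posterior_mode(bimodal)) - 0.8), 0.05)
})

test_that("HDR machinery matches the Gaussian closed form and nests", {
  set.seed(53)
  draws <- rnorm(1e5, 0.5, 0.01)
  h95 <- hdr(draws, 0.95)
  expect_equal(nrow(h95), 1)
  expect_lt(abs(h95[1, "lo"] - (0.5 - 1.959964 * 0.01)), 0.003)
  expect_lt(abs(h95[1, "hi"] - (0.5 + 1.959964 * 0.01)), 0.003)
  h50 <- hdr(draws, 0.50); h75 <- hdr(draws, 0.75)
  within <- function(inner, outer)
    all(apply(inner, 1, function(iv)
      any(outer[, "lo"] <= iv["lo"] + 1e-9 &
            outer[, "hi"] >= iv["hi"] - 1e-9)))
  expect_true(within(h50, h75))
  expect_true(within(h75, h95))
})

test_that("HDR of uniform draws covers ~95% of the support and splits on
           bimodal draws", {
  set.seed(59)
  u <- runif(2e5)
  h <- hdr(u, 0.95)
  expect_lt(abs(sum(h[, "hi"] - h[, "lo"]) - 0.95), 0.03)
  bim <- c(rnorm(5e4, 0.2, 0.03), rnorm(5e4, 0.8, 0.03))
  hb <- hdr(bim, 0.95)
  expect_gte(nrow(hb), 2)
})

test_that("HDR nesting holds on an actual fit", {
  sc <- three_source_scenario(seed = 29)
  src <- source_groups(generate_sources(sc))
  cons <- generate_consumers(sc, "period3")
  fit <- fit_mixing_model(cons, src, config = mixing_config(
    n_iter = 8000, burn_in = 2000, seed = 2))
  s <- summary(fit)
  for (g in src$names) {
    h <- s$hdr[[g]]
    expect_true(h$hdr50[1, "lo"] >= h$hdr95[1, "lo"] - 1e-9)
    expect_true(h$hdr50[1, "hi"] <= h$hdr95[1, "hi"] + 1e-9)
  }
})

test_that("overlap lettering implements the compact letter display", {
  disj <- list(p1 = cbind(lo = 0.1, hi = 0.2), p2 = cbind(lo = 0.5, hi = 0.6))
  expect_equal(unname(hdr_overlap_letters(disj)), c("a", "b"))
  same <- list(p1 = cbind(lo = 0.1, hi = 0.3), p2 = cbind(lo = 0.1, hi = 0.3))
  expect_equal(unname(hdr_overlap_letters(same)), c("a", "a"))
  path <- list(p1 = cbind(lo = 0.10, hi = 0.30),
               p2 = cbind(lo = 0.25, hi = 0.50),
               p3 = cbind(lo = 0.45, hi = 0.70))
  expect_equal(unname(hdr_overlap_letters(path)), c("a", "ab", "b"))
})

test_that("fit methods are coherent with the stored draws", {
  sc <- three_source_scenario(seed = 31)
  src <- source_groups(generate_sources(sc))
  cons <- generate_consumers(sc, "period3")
  fit <- fit_mixing_model(cons, src, config = mixing_config(
    n_iter = 8000, burn_in = 2000, seed = 4))
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  pr <- predict(fit)
  expect_equal(pr$channel, fit$channels)
  res <- residuals(fit)
  expect_equal(dim(res), dim(fit$consumers))
  expect_equal(unname(res[1, ]),
               unname(fit$consumers[1, ] - pr$mean))
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(dim(sim), c(50, length(fit$channels)))
  # simulated consumers resemble observed ones
  expect_lt(max(abs(colMeans(sim) - colMeans(fit$consumers))), 1.5)
  expect_output(print(fit), "mixing model fit")
  expect_output(print(summary(fit)), "Diet proportions")
})
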