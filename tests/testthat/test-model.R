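test_that("cp_support enumerates admissible onset indices", {
  expect_equal(cp_support(18), 3:15)
  expect_length(cp_support(18), 13L)
  expect_equal(cp_support(6), 3L)
  expect_error(cp_support(5), "cannot hold")
})

test_that("rho = 0 reduces the likelihood to independent normals", {
  s <- ab_series(c(0, 0, 0, 1, 1, 1), 3)
  p <- bucp_params(0, 1, sigma = 1, rho = 0, cp = 3)
  # zero residuals, unit sigma: -6 log(sqrt(2 pi))
  expect_equal(log_likelihood(s, p), -3 * log(2 * pi))
  set.seed(1)
  s2 <- ab_series(rnorm(12, 50, 3), 6)
  p2 <- bucp_params(49, 51, sigma = 2.5, rho = 0, cp = 5)
  mu <- ifelse(0:11 < 5, 49, 51)
  expect_equal(log_likelihood(s2, p2),
               sum(dnorm(s2$score, mu, 2.5, log = TRUE)))
})

test_that("the stationary AR(1) likelihood matches the dense MVN oracle", {
  set.seed(7)
  for (i in 1:10) {
    s <- ab_series(rnorm(10, 60, 4), sample(3:7, 1))
    p <- bucp_params(runif(1, 55, 65), runif(1, 55, 65),
                     sigma = runif(1, 0.5, 4), rho = runif(1, -0.9, 0.9),
                     cp = sample(3:7, 1))
    expect_equal(log_likelihood(s, p), mvn_ar1_loglik(s, p),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to joint translation of series and intercepts", {
  set.seed(3)
  s <- ab_series(rnorm(18, 70, 3), 10)
  p <- bucp_params(69, 72, sigma = 2, rho = 0.3, cp = 9)
  s_shift <- ab_series(s$score + 17.5, 10)
  p_shift <- bucp_params(69 + 17.5, 72 + 17.5, sigma = 2, rho = 0.3, cp = 9)
  expect_equal(log_likelihood(s_shift, p_shift), log_likelihood(s, p))
})

test_that("rho = 0 likelihood is symmetric under phase-label reversal", {
  set.seed(4)
  y <- rnorm(18, 70, 3)
  s <- ab_series(y, 10)
  p <- bucp_params(69, 72, sigma = 2, rho = 0, cp = 7)
  s_rev <- ab_series(rev(y), 18 - 10)
  p_rev <- bucp_params(72, 69, sigma = 2, rho = 0, cp = 18 - 7)
  expect_equal(log_likelihood(s_rev, p_rev), log_likelihood(s, p))
})

test_that("rho = 0 likelihood factorizes across phases at every valid cp", {
  set.seed(5)
  y <- rnorm(18, 70, 3)
  for (cp in cp_support(18)) {
    p <- bucp_params(69, 72, sigma = 2, rho = 0, cp = cp)
    full <- log_likelihood(ab_series(y, 10), p)
    a <- sum(dnorm(y[seq_len(cp)], 69, 2, log = TRUE))
    b <- sum(dnorm(y[(cp + 1):18], 72, 2, log = TRUE))
    expect_equal(full, a + b)
  }
})

test_that("gapped series use exact AR(1) skip decay", {
  # dropping an interior observation must equal the likelihood computed
  # from the dense MVN of the remaining coordinates
  set.seed(6)
  y <- rnorm(12, 50, 2)
  keep <- c(1:6, 8:12)  # week 6 (0-based) missing
  s_gap <- ab_series(y[keep], 5, timepoints = (0:11)[keep])
  p <- bucp_params(49, 52, sigma = 1.5, rho = 0.6, cp = 5)
  n <- length(keep)
  wk <- (0:11)[keep]
  lag <- abs(outer(wk, wk, "-"))
  S <- p$sigma^2 * p$rho^lag / (1 - p$rho^2)
  mu <- ifelse(seq_len(n) - 1 < p$cp, p$beta11, p$beta21)
  L <- chol(S)
  d <- s_gap$score - mu
  oracle <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) +
                      sum(backsolve(L, d, transpose = TRUE)^2))
  expect_equal(log_likelihood(s_gap, p), oracle, tolerance = 1e-8)
})

test_that("log_prior sums independent components and respects support", {
  # flat rho prior: rho contributes log(1/2)
  pri <- bucp_priors(beta_mean = 70, beta_sd = 30, sigma_upper = 15,
                     rho_prior_sd = Inf)
  p <- bucp_params(69, 72, sigma = 2, rho = 0.5, cp = 9)
  manual <- dnorm(69, 70, 30, log = TRUE) + dnorm(72, 70, 30, log = TRUE) -
    log(15) + log(1 / 2) - log(13)
  expect_equal(log_prior(p, pri, n = 18), manual)
  # shrinkage rho prior: truncated-normal density replaces the log(1/2)
  pri_s <- bucp_priors(beta_mean = 70, beta_sd = 30, sigma_upper = 15,
                       rho_prior_sd = 0.3)
  trunc_const <- pnorm(1, 0, 0.3) - pnorm(-1, 0, 0.3)
  expect_equal(log_prior(p, pri_s, 18) - log_prior(p, pri, 18),
               dnorm(0.5, 0, 0.3, log = TRUE) - log(trunc_const) - log(1 / 2))
  # prior mode is maximal among a grid of candidates
  at_mode <- log_prior(bucp_params(70, 70, 2, 0, 9), pri_s, 18)
  for (b in c(40, 60, 80, 100)) {
    for (r in c(-0.5, 0, 0.5)) {
      expect_lte(log_prior(bucp_params(b, b, 2, r, 9), pri_s, 18), at_mode)
    }
  }
  # out-of-support cases
  expect_identical(log_prior(bucp_params(70, 70, 2, 0, cp = 16), pri, 18), -Inf)
  expect_identical(log_prior(bucp_params(70, 70, 16, 0, cp = 9), pri, 18), -Inf)
})
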