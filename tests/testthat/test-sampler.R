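test_that("mcmc_config enforces multi-chain and minimum draws", {
  expect_error(mcmc_config(chains = 1), "at least 2 chains")
  expect_error(mcmc_config(iterations = 500), "at least 1000")
})

test_that("chain starts are overdispersed, distinct, deterministic and in-support", {
  sc <- scenario("stable_null", seed = 2)
  pri <- default_priors(sc$series)
  cfg <- mcmc_config(seed = 11)
  st1 <- initialize_chains(sc$series, pri, cfg)
  st2 <- initialize_chains(sc$series, pri, cfg)
  expect_identical(st1, st2)
  expect_length(st1, 4L)
  expect_equal(length(unique(vapply(st1, `[[`, 0, "beta11"))), 4L)
  support <- cp_support(18)
  for (st in st1) {
    expect_true(st$sigma > 0 && st$sigma < pri$sigma_upper)
    expect_true(abs(st$rho) < 1)
    expect_true(st$cp %in% support)
  }
})

test_that("sampling is deterministic given the seed", {
  sc <- scenario("responder", seed = 4)
  cfg <- mcmc_config(iterations = 1000, burn_in = 200, seed = 21)
  d1 <- suppressWarnings(sample_posterior(sc$series, mcmc = cfg))
  d2 <- suppressWarnings(sample_posterior(sc$series, mcmc = cfg))
  expect_identical(d1$chains, d2$chains)
})

test_that("a null series recovers a phase contrast indistinguishable from zero", {
  sc <- scenario("stable_null", seed = 31)
  d <- sample_posterior(sc$series,
                        mcmc = mcmc_config(iterations = 10000, burn_in = 5000,
                                           seed = 32))
  diff <- pooled_draws(d, "beta21") - pooled_draws(d, "beta11")
  expect_lt(abs(mean(diff)), 2 * sd(diff))
})

test_that("a near-noise-free step pins the change point", {
  p <- true_params(78, 82.5, sigma = 0.05, rho = 0, cp = 10)
  s <- simulate_series(p, seed = 41)
  d <- suppressWarnings(
    sample_posterior(s, mcmc = mcmc_config(iterations = 5000, burn_in = 2000,
                                           seed = 42)))
  pmf <- cp_pmf(d)
  expect_gte(pmf[["10"]], 0.99)
})

test_that("Metropolis acceptance rates are within tuning bounds on scenario fits", {
  for (name in c("responder", "stable_null", "drifting_null")) {
    sc <- scenario(name, seed = 51)
    expect_no_warning(
      d <- sample_posterior(sc$series,
                            mcmc = mcmc_config(iterations = 4000,
                                               burn_in = 2000, seed = 52)))
    ok <- d$accept[is.finite(d$accept)]
    expect_true(all(ok >= 0.15 & ok <= 0.6))
  }
})

test_that("doubling the iterations leaves posterior means stable", {
  sc <- scenario("drifting_null", seed = 61)
  d1 <- sample_posterior(sc$series,
                         mcmc = mcmc_config(iterations = 10000, burn_in = 5000,
                                            seed = 62))
  d2 <- sample_posterior(sc$series,
                         mcmc = mcmc_config(iterations = 20000, burn_in = 5000,
                                            seed = 63))
  for (par in c("beta11", "beta21", "sigma", "rho", "cp", "es")) {
    x1 <- pooled_draws(d1, par); x2 <- pooled_draws(d2, par)
    se <- sqrt(mcse(x1)^2 + mcse(x2)^2)
    expect_lt(abs(mean(x1) - mean(x2)), 2 * se)
  }
})

test_that("every draw satisfies the parameter support", {
  sc <- scenario("drifting_null", seed = 71)
  d <- sample_posterior(sc$series,
                        mcmc = mcmc_config(iterations = 2000, burn_in = 1000,
                                           seed = 72))
  support <- cp_support(18)
  for (m in d$chains) {
    expect_equal(nrow(m), 2000L)
    expect_true(all(m[, "sigma"] > 0 & m[, "sigma"] < d$priors$sigma_upper))
    expect_true(all(abs(m[, "rho"]) < 1))
    expect_true(all(m[, "cp"] %in% support))
  }
})

test_that("draws export to CSV and read back equivalently", {
  sc <- scenario("responder", seed = 81)
  d <- suppressWarnings(
    sample_posterior(sc$series, mcmc = mcmc_config(iterations = 1000,
                                                   burn_in = 500, seed = 82)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(d, path)
  d2 <- read_draws_csv(path)
  expect_equal(length(d2$chains), 4L)
  for (j in 1:4) {
    expect_equal(unname(d2$chains[[j]]), unname(d$chains[[j]]),
                 tolerance = 1e-12)
  }
})
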