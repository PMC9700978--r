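test_that("effect-size draws standardize the phase contrast per draw", {
  # null identity: equal intercepts give es identically 0
  m <- t(replicate(200, draw_row(70, 70, runif(1, 1, 3))))
  expect_true(all(effect_size_draws(fake_draws(m, m)) == 0))
  # unit standardization on a single draw
  single <- matrix(draw_row(10, 12, 2), nrow = 1)
  expect_equal(effect_size_draws(fake_draws(single, single)), c(1, 1))
  # plug-in at published posterior means: (38.04 - 38.91) / 2.35
  plug <- matrix(draw_row(38.91, 38.04, 2.35), nrow = 1)
  es <- effect_size_draws(fake_draws(plug, plug))[1]
  expect_equal(es, -0.87 / 2.35)
  expect_lt(es, 0)                      # sign agrees with the reported -0.40
  expect_lt(abs(es - (-0.40)), 0.15)    # magnitude in the reported ballpark
})

test_that("PSRF matches its formula in degenerate and separated cases", {
  n <- 4
  # two identical chains: B = 0, statistic reduces to sqrt((n-1)/n)
  expect_equal(psrf(list(c(1, 2, 3, 4), c(1, 2, 3, 4))), sqrt((n - 1) / n))
  # internally constant but separated chains: unbounded
  expect_gt(psrf(list(rep(0, 4), rep(10, 4))), 3)
  # all draws identical everywhere: no Monte-Carlo variability, 1 by convention
  expect_equal(psrf(list(rep(2, 4), rep(2, 4))), 1)
  # direct formula evaluation on arbitrary chains
  a <- c(1, 3, 2, 5); b <- c(2, 8, 6, 4)
  W <- (var(a) + var(b)) / 2
  B <- 4 * var(c(mean(a), mean(b)))
  expect_equal(psrf(list(a, b)), sqrt((3 / 4 * W + B / 4) / W))
  expect_error(psrf(list(a)), "2 chains")
})

test_that("long converged chains on a null scenario keep PSRF below 1.05", {
  sc <- scenario("stable_null", seed = 91)
  d <- sample_posterior(sc$series,
                        mcmc = mcmc_config(iterations = 10000, burn_in = 5000,
                                           seed = 92))
  for (par in c("beta11", "beta21", "sigma", "rho", "cp", "es")) {
    expect_lt(psrf(lapply(d$chains, function(m) m[, par])), 1.05)
  }
})

test_that("ci95 follows the equal-tailed type-7 percentile rule", {
  expect_equal(ci95(sample(1:1000)), c(lower = 25.975, upper = 975.025))
  expect_equal(ci95(rep(3.2, 100)), c(lower = 3.2, upper = 3.2))
  set.seed(12)
  z <- rnorm(100000)
  ci <- ci95(z)
  expect_lt(abs(ci[["lower"]] - (-1.96)), 0.02)
  expect_lt(abs(ci[["upper"]] - 1.96), 0.02)
  expect_error(ci95(rnorm(50)), "at least 100")
})

test_that("significance requires separated phase CIs and an es CI excluding zero", {
  # published case 1, total score: separated phases, positive es interval
  d1 <- decide_significance(c(77.52, 79.00), c(81.38, 83.49), c(1.47, 5.91))
  expect_true(d1[["significant"]])
  expect_false(d1[["ci_overlap"]])
  # published case 2, total score: overlapping phases, es interval spans 0
  d2 <- decide_significance(c(64.52, 68.70), c(64.88, 68.73), c(-0.83, 0.95))
  expect_false(d2[["significant"]])
  expect_true(d2[["ci_overlap"]])
  # touching intervals count as overlap (closed-interval convention)
  d3 <- decide_significance(c(0, 1), c(1, 2), c(1, 2))
  expect_true(d3[["ci_overlap"]])
  expect_false(d3[["significant"]])
  # both rules must fire
  d4 <- decide_significance(c(0, 1), c(5, 6), c(-0.2, 3))
  expect_false(d4[["significant"]])
  expect_true(d4[["es_excludes_zero"]] == FALSE)
  expect_error(decide_significance(c(1, 0), c(0, 1), c(0, 1)), "malformed")
})

test_that("widening intervals can only destroy significance, never create it", {
  set.seed(13)
  for (i in 1:50) {
    a <- sort(runif(2, 0, 10)); b <- sort(runif(2, 0, 10))
    es <- sort(runif(2, -2, 6))
    base <- decide_significance(a, b, es)
    wide <- decide_significance(a + c(-0.5, 0.5), b + c(-0.5, 0.5), es)
    if (wide[["significant"]]) expect_true(base[["significant"]])
    # shifting the es interval across 0 flips the exclusion flag exactly once
    shifted <- decide_significance(a, b, es - min(0, es[1]) + 0.01)
    expect_true(shifted[["es_excludes_zero"]])
  }
})

test_that("summarize_draws produces a coherent report", {
  sc <- scenario("responder", seed = 14)
  d <- sample_posterior(sc$series,
                        mcmc = mcmc_config(iterations = 5000, burn_in = 2000,
                                           seed = 15))
  rep <- summarize_draws(d)
  expect_s3_class(rep, "bucp_report")
  expect_setequal(rep$parameter,
                  c("beta11", "beta21", "sigma", "rho", "cp", "es"))
  expect_true(all(rep$lower <= rep$mean & rep$mean <= rep$upper))
  fl <- report_flags(rep)
  expect_identical(fl[["converged"]], max(rep$psrf) < 1.05)
  expect_identical(fl[["significant"]],
                   !fl[["ci_overlap"]] && fl[["es_excludes_zero"]])
  # pooled summary of es equals the mean of the per-draw effect sizes
  expect_equal(rep["es", "mean"], mean(effect_size_draws(d)))
})

test_that("swapping phase labels negates es draws and preserves CI widths", {
  sc <- scenario("responder", seed = 16)
  d <- sample_posterior(sc$series,
                        mcmc = mcmc_config(iterations = 5000, burn_in = 2000,
                                           seed = 17))
  d_swap <- d
  d_swap$chains <- lapply(d$chains, function(m) {
    m2 <- m
    m2[, "beta11"] <- m[, "beta21"]
    m2[, "beta21"] <- m[, "beta11"]
    m2[, "es"] <- -m[, "es"]
    m2
  })
  expect_equal(effect_size_draws(d_swap), -effect_size_draws(d))
  ci <- ci95(effect_size_draws(d))
  ci_swap <- ci95(effect_size_draws(d_swap))
  expect_equal(diff(unname(ci_swap)), diff(unname(ci)), tolerance = 1e-10)
})
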