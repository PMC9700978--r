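# Shared test utilities: independent likelihood oracle, batch-means
# Monte-Carlo standard errors, and small fixture builders.

# Dense multivariate-normal AR(1) log-density, Sigma_ij =
# sigma^2 rho^|i-j| / (1 - rho^2). Independent of the package's
# recursive likelihood and of the compiled sampler.
mvn_ar1_loglik <- function(series, params) {
  y <- series$score
  n <- length(y)
  mu <- ifelse(seq_len(n) - 1L < params$cp, params$beta11, params$beta21)
  lag <- abs(outer(seq_len(n), seq_len(n), "-"))
  S <- params$sigma^2 * params$rho^lag / (1 - params$rho^2)
  L <- chol(S)
  d <- y - mu
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) +
            sum(backsolve(L, d, transpose = TRUE)^2))
}

# Batch-means Monte-Carlo standard error of the mean of (possibly
# autocorrelated) draws.
mcse <- function(x, n_batch = 50L) {
  bs <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(bs * n_batch)], nrow = bs))
  stats::sd(bm) / sqrt(n_batch)
}

# Wrap plain per-chain draw matrices as a bucp_draws object (for
# diagnostics tests that do not need a real sampler run).
fake_draws <- function(...) {
  chains <- lapply(list(...), function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("beta11", "beta21", "sigma", "rho", "cp", "es")
    m
  })
  structure(list(chains = chains, accept = NULL, config = NULL,
                 priors = NULL, rho_fixed = NULL,
                 series_label = "test", n = NA_integer_),
            class = "bucp_draws")
}

# One draws row (beta11, beta21, sigma, rho, cp) with es appended.
draw_row <- function(b1, b2, sigma, rho = 0, cp = 10) {
  c(b1, b2, sigma, rho, cp, (b2 - b1) / sigma)
}

# A random valid ABC-DS item vector.
random_items <- function() sample(1:9, 13, replace = TRUE)

quiet_fit <- function(...) suppressWarnings(bucp_fit(...))
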