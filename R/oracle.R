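# Brute-force reference posteriors, independent of the MCMC code path.
#
# The intercepts are conjugate under the whitened AR(1) regression, so
# they are integrated out analytically for every block (cp, rho, sigma);
# sigma (and rho, when gridded) are handled by midpoint quadrature under
# their uniform priors. enumerate_cp_posterior() is the rho = 0 case,
# exact up to the sigma quadrature; grid_posterior_mean() adds a rho grid
# for coverage at the cost of quadrature error in rho.

# Whitened sufficient statistics of the intercept regression at fixed
# (rho, cp); mirrors the compiled sampler's transformation.
whiten_stats_r <- function(y, rho, cp) {
  n <- length(y)
  t_ <- seq_len(n) - 1L
  a <- as.numeric(t_ < cp)
  w0 <- sqrt(1 - rho^2)
  xa <- c(w0 * a[1L], a[-1L] - rho * a[-n])
  xb <- c(w0 * (1 - a[1L]), (1 - a[-1L]) - rho * (1 - a[-n]))
  z <- c(w0 * y[1L], y[-1L] - rho * y[-n])
  list(m11 = sum(xa * xa), m12 = sum(xa * xb), m22 = sum(xb * xb),
       xz1 = sum(xa * z), xz2 = sum(xb * z), zz = sum(z * z), n = n)
}

# Marginal log-likelihood (intercepts integrated out) and conditional
# posterior intercept means over a vector of sigma values, for one
# (rho, cp) block.
block_marginal <- function(stats, rho, sigma, beta_mean, beta_sd) {
  s2 <- sigma^2
  tau2 <- beta_sd^2
  m0 <- beta_mean
  dd <- stats$zz - 2 * m0 * (stats$xz1 + stats$xz2) +
    m0^2 * (stats$m11 + 2 * stats$m12 + stats$m22)
  u1 <- stats$xz1 - m0 * (stats$m11 + stats$m12)
  u2 <- stats$xz2 - m0 * (stats$m12 + stats$m22)
  # A = (s2/tau2) I + M
  a11 <- s2 / tau2 + stats$m11
  a12 <- stats$m12
  a22 <- s2 / tau2 + stats$m22
  det_a <- a11 * a22 - a12^2
  quad <- (dd - (a22 * u1^2 - 2 * a12 * u1 * u2 + a11 * u2^2) / det_a) / s2
  # |I + (tau2/s2) M| = det(A) * (tau2/s2)^2
  logdet <- log(det_a) + 2 * log(tau2 / s2)
  logml <- -stats$n / 2 * log(2 * pi * s2) + 0.5 * log(1 - rho^2) -
    0.5 * logdet - 0.5 * quad
  # conditional posterior means of (beta11, beta21): solve (M/s2 + I/tau2) m = b
  p11 <- stats$m11 / s2 + 1 / tau2
  p12 <- stats$m12 / s2
  p22 <- stats$m22 / s2 + 1 / tau2
  b1 <- stats$xz1 / s2 + m0 / tau2
  b2 <- stats$xz2 / s2 + m0 / tau2
  det_p <- p11 * p22 - p12^2
  m1 <- (p22 * b1 - p12 * b2) / det_p
  m2 <- (p11 * b2 - p12 * b1) / det_p
  list(logml = logml, m1 = m1, m2 = m2)
}

# Midpoint grid on (0, upper].
midpoints <- function(upper, k) (seq_len(k) - 0.5) * upper / k

#' Exact change-point posterior by enumeration (rho = 0)
#'
#' For each admissible change point, the intercepts are integrated out
#' analytically under their conjugate normal prior and sigma numerically
#' on a midpoint grid under its uniform prior; the resulting marginal
#' likelihoods are normalized into `P(cp | y)`. Exact up to the sigma
#' quadrature; used as the primary correctness gate for the sampler.
#'
#' @param series A complete [ab_series()].
#' @param priors A [bucp_priors()] object.
#' @param n_sigma Number of sigma quadrature points.
#' @return Named probability vector over [cp_support()] (names = onset
#'   indices); sums to 1.
#' @export
enumerate_cp_posterior <- function(series, priors, n_sigma = 400L) {
  stopifnot(inherits(series, "ab_series"), inherits(priors, "bucp_priors"))
  y <- series$score
  support <- cp_support(length(y), priors$min_per_phase)
  sig <- midpoints(priors$sigma_upper, n_sigma)
  logp <- vapply(support, function(cp) {
    st <- whiten_stats_r(y, 0, cp)
    lml <- block_marginal(st, 0, sig, priors$beta_mean, priors$beta_sd)$logml
    m <- max(lml)
    m + log(mean(exp(lml - m)))  # uniform sigma prior: average over grid
  }, 0)
  p <- exp(logp - max(logp))
  stats::setNames(p / sum(p), support)
}

#' Approximate full-posterior means by grid quadrature
#'
#' Enumerates the change point, grids rho and sigma (midpoint rule under
#' their uniform priors) and integrates the intercepts analytically per
#' block, yielding posterior means for all parameters and the per-draw
#' effect size `es = (beta21 - beta11) / sigma`. With `rho_grid = 0` its
#' change-point marginal coincides with [enumerate_cp_posterior()].
#'
#' @param series A complete [ab_series()].
#' @param priors A [bucp_priors()] object.
#' @param n_sigma Number of sigma quadrature points.
#' @param rho_grid Vector of rho values (an equally spaced grid over
#'   (-1, 1), or just 0); quadrature nodes weighted by the rho prior.
#' @return List with `means` (named vector over beta11, beta21, sigma,
#'   rho, cp, es) and `cp_posterior` (named probability vector).
#' @export
grid_posterior_mean <- function(series, priors, n_sigma = 200L,
                                rho_grid = seq(-0.95, 0.95, length.out = 39L)) {
  stopifnot(inherits(series, "ab_series"), inherits(priors, "bucp_priors"))
  y <- series$score
  support <- cp_support(length(y), priors$min_per_phase)
  sig <- midpoints(priors$sigma_upper, n_sigma)
  n_blocks <- length(support) * length(rho_grid) * length(sig)
  if (n_blocks > 1e7) stop("grid too large (", n_blocks, " points)", call. = FALSE)

  logw <- numeric(0); cps <- numeric(0); rhos <- numeric(0); sigs <- numeric(0)
  mb1 <- numeric(0); mb2 <- numeric(0)
  for (cp in support) {
    for (rho in rho_grid) {
      st <- whiten_stats_r(y, rho, cp)
      bm <- block_marginal(st, rho, sig, priors$beta_mean, priors$beta_sd)
      logw <- c(logw, bm$logml + log_rho_prior(rho, priors$rho_prior_sd))
      mb1 <- c(mb1, bm$m1); mb2 <- c(mb2, bm$m2)
      cps <- c(cps, rep(cp, length(sig)))
      rhos <- c(rhos, rep(rho, length(sig)))
      sigs <- c(sigs, sig)
    }
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  means <- c(
    beta11 = sum(w * mb1),
    beta21 = sum(w * mb2),
    sigma = sum(w * sigs),
    rho = sum(w * rhos),
    cp = sum(w * cps),
    es = sum(w * (mb2 - mb1) / sigs)
  )
  cp_post <- vapply(support, function(cp) sum(w[cps == cp]), 0)
  list(means = means, cp_posterior = stats::setNames(cp_post, support))
}

#' Total-variation distance between two change-point distributions
#'
#' @param p,q Probability vectors over the same named support (an
#'   empirical pmf and an enumerated posterior, say); missing categories
#'   count as zero mass.
#' @return TV distance in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  sum(abs(pv - qv)) / 2
}

#' Empirical change-point pmf from posterior draws
#'
#' @param draws A `bucp_draws` object.
#' @return Named probability vector over the observed cp values.
#' @export
cp_pmf <- function(draws) {
  x <- pooled_draws(draws, "cp")
  tab <- table(x)
  stats::setNames(as.numeric(tab) / length(x), names(tab))
}
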