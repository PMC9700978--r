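# The BUCP probability model.
#
# Observation model: y_t ~ Normal(mu_t, .) with mu_t = beta11 before the
# change point and beta21 from it on; errors follow a stationary AR(1)
# process with innovation SD sigma and lag-1 autocorrelation rho. The
# change point cp is discrete: the 0-based index of the first observation
# at the phase-B level. The likelihood is the exact stationary AR(1)
# density (first residual at variance sigma^2 / (1 - rho^2)); a
# conditional-on-first-observation variant is available for sensitivity
# checks.

#' BUCP model parameters
#'
#' @param beta11 Phase-A intercept.
#' @param beta21 Phase-B intercept.
#' @param sigma Residual (innovation) SD, > 0.
#' @param rho Lag-1 autocorrelation, in (-1, 1).
#' @param cp Discrete change point: 0-based index of the first phase-B
#'   observation.
#' @return Object of class `bucp_params`.
#' @export
bucp_params <- function(beta11, beta21, sigma, rho, cp) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.finite(rho) || abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  structure(
    list(beta11 = beta11, beta21 = beta21, sigma = sigma, rho = rho,
         cp = as.integer(cp)),
    class = "bucp_params"
  )
}

#' Admissible change-point support
#'
#' All onset indices that leave at least `min_per_phase` observations in
#' each phase: `t` with `t >= min_per_phase` and `n - t >= min_per_phase`.
#'
#' @param n Series length.
#' @param min_per_phase Minimum observations per phase (default 3, the
#'   model's applicability rule).
#' @return Increasing integer vector of candidate onset indices.
#' @examples
#' cp_support(18)  # 3, 4, ..., 15
#' @export
cp_support <- function(n, min_per_phase = 3L) {
  n <- as.integer(n); m <- as.integer(min_per_phase)
  if (n < 2L * m) {
    stop("series of length ", n, " cannot hold ", m,
         " observations in each phase", call. = FALSE)
  }
  seq.int(m, n - m)
}

#' Prior specification for the BUCP model
#'
#' Independent priors: `Normal(beta_mean, beta_sd^2)` on both intercepts,
#' `Uniform(0, sigma_upper)` on sigma, a zero-centered
#' `Normal(0, rho_prior_sd^2)` truncated to (-1, 1) on rho, and a
#' discrete uniform over [cp_support()] on the change point.
#'
#' The rho shrinkage matters: a short AB series cannot distinguish a
#' level step from near-unit-root drift, so a flat prior on rho lets the
#' autocorrelation absorb the intervention effect and inflate the
#' phase-level intervals. The default scale 0.3 treats |rho| > 0.6 as
#' a priori unlikely for weekly behavioral ratings; `rho_prior_sd = Inf`
#' gives the flat Uniform(-1, 1) alternative for sensitivity analysis.
#'
#' @param beta_mean,beta_sd Normal hyperparameters shared by the two
#'   intercepts (outcome score units).
#' @param sigma_upper Upper bound of the uniform prior on sigma.
#' @param rho_prior_sd Scale of the truncated-normal prior on rho;
#'   `Inf` for Uniform(-1, 1).
#' @param min_per_phase Phase-length rule defining the change-point
#'   support.
#' @return Object of class `bucp_priors`.
#' @export
bucp_priors <- function(beta_mean, beta_sd, sigma_upper, rho_prior_sd = 0.3,
                        min_per_phase = 3L) {
  if (!is.finite(beta_sd) || beta_sd <= 0) stop("beta_sd must be > 0", call. = FALSE)
  if (!is.finite(sigma_upper) || sigma_upper <= 0) {
    stop("sigma_upper must be > 0", call. = FALSE)
  }
  if (is.na(rho_prior_sd) || rho_prior_sd <= 0) {
    stop("rho_prior_sd must be > 0 (Inf for a uniform rho prior)", call. = FALSE)
  }
  structure(
    list(beta_mean = beta_mean, beta_sd = beta_sd,
         sigma_upper = sigma_upper, rho_prior_sd = rho_prior_sd,
         min_per_phase = as.integer(min_per_phase)),
    class = "bucp_priors"
  )
}

# Log-density of the rho prior (truncated normal on (-1, 1), or the
# uniform limit).
log_rho_prior <- function(rho, rho_prior_sd) {
  if (abs(rho) >= 1) return(-Inf)
  if (!is.finite(rho_prior_sd)) return(log(1 / 2))
  z <- stats::pnorm(1, 0, rho_prior_sd) - stats::pnorm(-1, 0, rho_prior_sd)
  stats::dnorm(rho, 0, rho_prior_sd, log = TRUE) - log(z)
}

#' Weakly informative default priors scaled to the observed series
#'
#' Intercepts `Normal(mean(y), (10 * sd(y))^2)`, sigma
#' `Uniform(0, 5 * sd(y))`, rho `Uniform(-1, 1)`, change point discrete
#' uniform over the admissible support. Centering on the outcome's own
#' scale keeps the priors weak without being improper.
#'
#' @param series An [ab_series()].
#' @param rho_prior_sd Scale of the truncated-normal rho prior (see
#'   [bucp_priors()]).
#' @param min_per_phase Phase-length rule.
#' @return A [bucp_priors()] object.
#' @export
default_priors <- function(series, rho_prior_sd = 0.3, min_per_phase = 3L) {
  y <- series$score
  s <- stats::sd(y)
  if (!is.finite(s) || s <= 0) {
    stop("series has zero variance; priors cannot be scaled to it", call. = FALSE)
  }
  bucp_priors(beta_mean = mean(y), beta_sd = 10 * s, sigma_upper = 5 * s,
              rho_prior_sd = rho_prior_sd, min_per_phase = min_per_phase)
}

# Phase means at a candidate change point, on the observation index scale.
phase_means <- function(series, beta11, beta21, cp) {
  ifelse(seq_along(series$score) - 1L < cp, beta11, beta21)
}

#' Exact AR(1) log-likelihood of an AB series under BUCP parameters
#'
#' Stationary Gaussian AR(1) density of the residuals
#' `e_t = y_t - mu_t(cp)`: the first residual has variance
#' `sigma^2 / (1 - rho^2)`; each later one is
#' `Normal(rho^d * e_prev, sigma^2 * (1 - rho^(2d)) / (1 - rho^2))` where
#' `d` is the week gap to the previous observation (1 for a complete
#' series; larger gaps decay exactly).
#'
#' @param series An [ab_series()].
#' @param params A [bucp_params()] object.
#' @param conditional Condition on the first observation instead of using
#'   its stationary density (sensitivity-check variant; default FALSE).
#' @return Log-likelihood (finite for all valid inputs).
#' @export
log_likelihood <- function(series, params, conditional = FALSE) {
  stopifnot(inherits(series, "ab_series"), inherits(params, "bucp_params"))
  y <- series$score
  n <- length(y)
  e <- y - phase_means(series, params$beta11, params$beta21, params$cp)
  sig2 <- params$sigma^2
  rho <- params$rho
  ll <- if (conditional) 0 else
    stats::dnorm(e[1L], 0, sqrt(sig2 / (1 - rho^2)), log = TRUE)
  if (n > 1L) {
    d <- diff(series$week)
    rd <- rho^d
    v <- sig2 * (1 - rho^(2 * d)) / (1 - rho^2)
    v[rho == 0] <- sig2  # 0^0 guard for d = 1 when rho = 0
    ll <- ll + sum(stats::dnorm(e[-1L], rd * e[-n], sqrt(v), log = TRUE))
  }
  ll
}

#' Joint log-prior of BUCP parameters
#'
#' Sum of the independent log prior densities; `-Inf` outside support
#' (sigma outside `(0, sigma_upper)`, `|rho| >= 1`, or cp outside the
#' admissible support for a series of length `n`).
#'
#' @param params A [bucp_params()] object.
#' @param priors A [bucp_priors()] object.
#' @param n Series length (defines the change-point support).
#' @return Log prior density.
#' @export
log_prior <- function(params, priors, n) {
  support <- cp_support(n, priors$min_per_phase)
  if (!(params$cp %in% support)) return(-Inf)
  if (params$sigma <= 0 || params$sigma >= priors$sigma_upper) return(-Inf)
  if (abs(params$rho) >= 1) return(-Inf)
  stats::dnorm(params$beta11, priors$beta_mean, priors$beta_sd, log = TRUE) +
    stats::dnorm(params$beta21, priors$beta_mean, priors$beta_sd, log = TRUE) +
    -log(priors$sigma_upper) +                       # sigma ~ U(0, upper)
    log_rho_prior(params$rho, priors$rho_prior_sd) + # truncated normal / uniform
    -log(length(support))                            # cp ~ discrete uniform
}
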