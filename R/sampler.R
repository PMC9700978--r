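# Multi-chain MCMC front end over the compiled Gibbs sweep.
#
# Seed policy: the master seed seeds R's RNG once, from which per-chain
# substream seeds are drawn; each chain then reseeds R's RNG with its own
# substream seed before running. Overdispersed starts are derived from the
# master seed before the substreams are drawn.

#' MCMC run configuration
#'
#' Defaults follow the analysis convention of 4 chains and 120,000 total
#' retained draws (30,000 post-burn-in per chain) with a burn-in of 5,000
#' per chain. Step sizes are initial values for the Metropolis updates of
#' sigma (log scale) and rho (atanh scale); when `adapt = TRUE` they are
#' tuned toward a 0.44 acceptance rate during burn-in and frozen after,
#' preserving detailed balance over the retained draws.
#'
#' @param chains Number of chains (>= 2; the PSRF needs several).
#' @param iterations Post-burn-in draws per chain (>= 1000).
#' @param burn_in Discarded initial iterations per chain.
#' @param seed Master integer seed.
#' @param step_sigma,step_rho Initial Metropolis standard deviations.
#' @param adapt Adapt step sizes during burn-in.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iterations = 30000L, burn_in = 5000L,
                        seed = 1L, step_sigma = 0.3, step_rho = 0.5,
                        adapt = TRUE) {
  chains <- as.integer(chains)
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (chains < 2L) stop("need at least 2 chains for PSRF", call. = FALSE)
  if (iterations < 1000L) stop("need at least 1000 retained draws per chain", call. = FALSE)
  structure(
    list(chains = chains, iterations = iterations, burn_in = burn_in,
         seed = as.integer(seed), step_sigma = step_sigma,
         step_rho = step_rho, adapt = isTRUE(adapt)),
    class = "mcmc_config"
  )
}

#' Overdispersed chain starting points
#'
#' Intercepts start at the designed phase sample means plus
#' `Normal(0, sd(y)/2)` jitter; sigma at `sd(y)` times a dispersion
#' factor cycling over \{1, 0.5, 2, 1.5\} (capped below `sigma_upper`);
#' rho cycles over \{0, -0.5, 0.5, 0.25\}; the change point is spread
#' across quantiles of its support. Deterministic given the seed.
#'
#' @param series An [ab_series()].
#' @param priors A [bucp_priors()] object.
#' @param mcmc An [mcmc_config()] object.
#' @param rho_fixed If non-NULL, all chains start (and stay) at this rho.
#' @return List of length `chains`; each element a list with
#'   `beta11, beta21, sigma, rho, cp`.
#' @export
initialize_chains <- function(series, priors, mcmc, rho_fixed = NULL) {
  y <- series$score
  n <- length(y)
  support <- cp_support(n, priors$min_per_phase)
  s <- stats::sd(y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mcmc$seed)
  disp <- c(1, 0.5, 2, 1.5)
  rhos <- c(0, -0.5, 0.5, 0.25)
  qs <- stats::quantile(support, seq(0.1, 0.9, length.out = mcmc$chains),
                        type = 1, names = FALSE)
  lapply(seq_len(mcmc$chains), function(j) {
    k <- (j - 1L) %% 4L + 1L
    list(
      beta11 = mean(phase_a(series)) + stats::rnorm(1, 0, s / 2),
      beta21 = mean(phase_b(series)) + stats::rnorm(1, 0, s / 2),
      sigma = min(s * disp[k], 0.9 * priors$sigma_upper),
      rho = if (is.null(rho_fixed)) rhos[k] else rho_fixed,
      cp = as.integer(qs[j])
    )
  })
}

#' Draw from the BUCP posterior by multi-chain MCMC
#'
#' One sweep updates, in order: the change point by an exact draw from
#' its discrete full conditional (support enumerated, conditional
#' likelihood normalized); the two intercepts by a conjugate
#' bivariate-normal draw under the whitened AR(1) regression; sigma and
#' rho by random-walk Metropolis on log and atanh scales. Chains start
#' overdispersed ([initialize_chains()]) and run independently on
#' substream seeds derived from the master seed.
#'
#' Post-burn-in Metropolis acceptance rates outside \[0.15, 0.6\] trigger
#' a tuning warning.
#'
#' @param series A complete [ab_series()] (no week gaps).
#' @param priors A [bucp_priors()] object; defaults to
#'   [default_priors()] of the series.
#' @param mcmc An [mcmc_config()] object.
#' @param rho_fixed Optionally fix rho at a value (e.g. 0) instead of
#'   sampling it; used for exact-oracle comparisons.
#' @return Object of class `bucp_draws`: list with `chains` (a list of
#'   `iterations x 6` matrices with columns beta11, beta21, sigma, rho,
#'   cp, es), `accept` (per-chain acceptance rates), `config`, `priors`,
#'   `series_label`, `n`.
#' @export
sample_posterior <- function(series, priors = default_priors(series),
                             mcmc = mcmc_config(), rho_fixed = NULL) {
  stopifnot(inherits(series, "ab_series"), inherits(priors, "bucp_priors"),
            inherits(mcmc, "mcmc_config"))
  if (!is_complete(series)) {
    stop("sampler requires a complete weekly series (no gaps)", call. = FALSE)
  }
  y <- series$score
  n <- length(y)
  support <- cp_support(n, priors$min_per_phase)
  starts <- initialize_chains(series, priors, mcmc, rho_fixed = rho_fixed)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max, mcmc$chains)

  chains <- vector("list", mcmc$chains)
  accept <- matrix(NA_real_, mcmc$chains, 2,
                   dimnames = list(NULL, c("sigma", "rho")))
  for (j in seq_len(mcmc$chains)) {
    st <- starts[[j]]
    set.seed(chain_seeds[j])
    out <- bucp_gibbs_chain(
      y, as.integer(support),
      priors$beta_mean, priors$beta_sd, priors$sigma_upper,
      mcmc$iterations, mcmc$burn_in,
      st$beta11, st$beta21, st$sigma, st$rho, st$cp,
      mcmc$step_sigma, mcmc$step_rho, mcmc$adapt,
      !is.null(rho_fixed), if (is.null(rho_fixed)) 0 else rho_fixed,
      priors$rho_prior_sd)
    d <- out$draws
    es <- (d[, 2] - d[, 1]) / d[, 3]
    m <- cbind(d, es)
    colnames(m) <- c("beta11", "beta21", "sigma", "rho", "cp", "es")
    chains[[j]] <- m
    accept[j, ] <- c(out$accept_sigma, out$accept_rho)
  }
  bad <- accept[is.finite(accept)]
  if (length(bad) && (any(bad < 0.15) || any(bad > 0.6))) {
    warning("Metropolis acceptance rate outside [0.15, 0.6]; ",
            "consider retuning step sizes", call. = FALSE)
  }
  structure(
    list(chains = chains, accept = accept, config = mcmc, priors = priors,
         rho_fixed = rho_fixed, series_label = series$label, n = n),
    class = "bucp_draws"
  )
}

#' @export
print.bucp_draws <- function(x, ...) {
  cat(sprintf("BUCP posterior draws: %d chains x %d iterations (burn-in %d)\n",
              length(x$chains), x$config$iterations, x$config$burn_in))
  invisible(x)
}

#' Pooled parameter draws across chains
#'
#' @param draws A `bucp_draws` object.
#' @param parameter Column name (`"beta11"`, `"beta21"`, `"sigma"`,
#'   `"rho"`, `"cp"`, `"es"`).
#' @return Numeric vector of all post-burn-in draws, chains concatenated.
#' @export
pooled_draws <- function(draws, parameter) {
  stopifnot(inherits(draws, "bucp_draws"))
  unlist(lapply(draws$chains, function(m) m[, parameter]), use.names = FALSE)
}

#' Export posterior draws to CSV (one row per draw)
#'
#' Columns: chain, iter, beta11, beta21, sigma, rho, cp, es.
#' [read_draws_csv()] restores an equivalent `bucp_draws` object.
#'
#' @param draws A `bucp_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "bucp_draws"))
  tabs <- lapply(seq_along(draws$chains), function(j) {
    m <- draws$chains[[j]]
    data.frame(chain = j, iter = seq_len(nrow(m)), m)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws_csv()]
#'
#' @param path CSV path.
#' @return A `bucp_draws` object (chains and draws only; no config).
#' @export
read_draws_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("chain", "iter", "beta11", "beta21", "sigma", "rho", "cp", "es")
  if (!all(need %in% names(df))) {
    stop("not a draws CSV (missing columns)", call. = FALSE)
  }
  chains <- lapply(split(df, df$chain), function(d) {
    as.matrix(d[, c("beta11", "beta21", "sigma", "rho", "cp", "es")])
  })
  structure(list(chains = unname(chains), accept = NULL, config = NULL,
                 priors = NULL, rho_fixed = NULL, series_label = NA_character_,
                 n = NA_integer_),
            class = "bucp_draws")
}
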