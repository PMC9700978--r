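# Convergence diagnostics, posterior summaries, the effect-size
# posterior, and the credible-interval significance decision rules.

#' Effect-size posterior draws
#'
#' Standardized mean difference between the phase intercepts, computed
#' per posterior draw as `es = (beta21 - beta11) / sigma` and pooled
#' across chains. The sign convention makes a phase-B improvement
#' positive (on scales where higher = milder, as with the ABC-DS);
#' computing it per draw yields a genuine posterior distribution for es
#' rather than a ratio of posterior means.
#'
#' @param draws A `bucp_draws` object.
#' @return Numeric vector of pooled es draws.
#' @export
effect_size_draws <- function(draws) {
  stopifnot(inherits(draws, "bucp_draws"))
  unlist(lapply(draws$chains, function(m) (m[, "beta21"] - m[, "beta11"]) / m[, "sigma"]),
         use.names = FALSE)
}

#' Gelman-Rubin potential scale reduction factor (PSRF)
#'
#' Classic two-part PSRF `sqrt((((n-1)/n) W + B/n) / W)` with `W` the
#' mean within-chain variance and `B` the between-chain variance of the
#' chain means (times n). Two degenerate cases are handled by convention:
#' if every draw in every chain is identical the parameter carries no
#' Monte-Carlo variability and 1 is returned; if chains are internally
#' constant but disagree (`W = 0`, `B > 0`) `Inf` is returned.
#'
#' @param chains List of equal-length numeric vectors (one per chain), or
#'   a matrix with one column per chain.
#' @param split Split each chain in half first (the split-chain variant,
#'   which also flags within-chain drift).
#' @return PSRF estimate (>= values near 1 for converged runs).
#' @export
psrf <- function(chains, split = FALSE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2L) stop("PSRF needs at least 2 chains", call. = FALSE)
  len <- lengths(chains)
  if (length(unique(len)) != 1L || len[1L] < 2L) {
    stop("chains must have equal lengths >= 2", call. = FALSE)
  }
  if (split) {
    half <- floor(len[1L] / 2)
    chains <- unlist(lapply(chains, function(x) {
      list(x[seq_len(half)], x[(length(x) - half + 1L):length(x)])
    }), recursive = FALSE)
  }
  n <- length(chains[[1L]])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (B == 0 && W == 0) return(1)
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Equal-tailed 95% credible interval of posterior draws
#'
#' 2.5th and 97.5th percentiles under R's default (type 7) quantile rule.
#'
#' @param x Numeric draws (at least 100, so the tails are estimable).
#' @return Named numeric `c(lower, upper)`, `lower <= upper`.
#' @export
ci95 <- function(x) {
  if (length(x) < 100L) {
    stop("need at least 100 draws for a 95% interval", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Apply the two credible-interval significance rules
#'
#' An intervention effect is declared significant when (1) the 95%
#' intervals of the phase-A and phase-B intercepts do not overlap
#' (closed-interval convention: touching endpoints count as overlap) and
#' (2) the 95% interval of the effect size excludes zero.
#'
#' @param ci_a,ci_b,ci_es Length-2 numeric intervals `(lower, upper)` for
#'   the phase-A intercept, phase-B intercept and effect size.
#' @return Named logical vector `c(ci_overlap, es_excludes_zero,
#'   significant)` with `significant = !ci_overlap & es_excludes_zero`.
#' @export
decide_significance <- function(ci_a, ci_b, ci_es) {
  for (ci in list(ci_a, ci_b, ci_es)) {
    if (length(ci) != 2L || anyNA(ci) || ci[1L] > ci[2L]) {
      stop("malformed interval: (", paste(ci, collapse = ", "), ")", call. = FALSE)
    }
  }
  overlap <- ci_a[1L] <= ci_b[2L] && ci_b[1L] <= ci_a[2L]
  excl0 <- ci_es[1L] > 0 || ci_es[2L] < 0
  c(ci_overlap = overlap, es_excludes_zero = excl0,
    significant = !overlap && excl0)
}

#' Summarize posterior draws into a fit report
#'
#' For each of beta11, beta21, sigma, rho, cp and es: pooled posterior
#' mean, SD and equal-tailed 95% interval, plus the across-chain PSRF.
#' The report carries the convergence flag (`max PSRF < psrf_threshold`)
#' and the significance decision of [decide_significance()] applied to
#' the phase-intercept and effect-size intervals.
#'
#' @param draws A `bucp_draws` object.
#' @param psrf_threshold Convergence cut-off on the maximum PSRF.
#' @param split_psrf Use the split-chain PSRF variant.
#' @return Object of class `bucp_report`: a data frame (parameter, mean,
#'   sd, lower, upper, psrf) with decision flags in its attributes.
#' @export
summarize_draws <- function(draws, psrf_threshold = 1.05, split_psrf = FALSE) {
  stopifnot(inherits(draws, "bucp_draws"))
  pars <- c("beta11", "beta21", "sigma", "rho", "cp", "es")
  rows <- lapply(pars, function(p) {
    x <- pooled_draws(draws, p)
    ci <- ci95(x)
    r <- psrf(lapply(draws$chains, function(m) m[, p]), split = split_psrf)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               lower = ci[["lower"]], upper = ci[["upper"]], psrf = r)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- report$parameter
  ci_a <- unlist(report["beta11", c("lower", "upper")], use.names = FALSE)
  ci_b <- unlist(report["beta21", c("lower", "upper")], use.names = FALSE)
  ci_es <- unlist(report["es", c("lower", "upper")], use.names = FALSE)
  dec <- decide_significance(ci_a, ci_b, ci_es)
  structure(report,
            class = c("bucp_report", "data.frame"),
            psrf_threshold = psrf_threshold,
            converged = max(report$psrf) < psrf_threshold,
            ci_overlap = unname(dec[["ci_overlap"]]),
            es_excludes_zero = unname(dec[["es_excludes_zero"]]),
            significant = unname(dec[["significant"]]),
            es_note = paste(
              "es computed per draw as (beta21 - beta11) / sigma, pooled across",
              "chains; positive = phase-B improvement. Printed formulations of",
              "the standardized difference sometimes state (beta11 - beta21)",
              "while reporting improvement as positive; this report fixes the",
              "improvement-positive convention."))
}

#' Decision flags of a fit report
#'
#' @param report A `bucp_report`.
#' @return Named logical vector `c(converged, ci_overlap,
#'   es_excludes_zero, significant)`.
#' @export
report_flags <- function(report) {
  stopifnot(inherits(report, "bucp_report"))
  c(converged = attr(report, "converged"),
    ci_overlap = attr(report, "ci_overlap"),
    es_excludes_zero = attr(report, "es_excludes_zero"),
    significant = attr(report, "significant"))
}

#' @export
print.bucp_report <- function(x, digits = 3, ...) {
  cat("BUCP fit report\n")
  df <- as.data.frame(x)
  df[, -1] <- lapply(df[, -1], round, digits = digits)
  print(df, row.names = FALSE)
  fl <- report_flags(x)
  cat(sprintf("converged (max PSRF < %.2f): %s | phase CIs overlap: %s | es CI excludes 0: %s\n",
              attr(x, "psrf_threshold"), fl[["converged"]],
              fl[["ci_overlap"]], fl[["es_excludes_zero"]]))
  cat("significant:", fl[["significant"]], "\n")
  invisible(x)
}

#' Write a fit report as text and as machine-readable CSV
#'
#' `write_report()` writes the human-readable layout; `write_report_csv()`
#' writes the summary grid plus one flag row block, re-readable with
#' [read.csv()].
#'
#' @param report A `bucp_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "bucp_report"))
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  print(report)
  cat("\nnote:", attr(report, "es_note"), "\n")
  sink()
  invisible(path)
}

#' @rdname write_report
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "bucp_report"))
  df <- as.data.frame(report)
  fl <- report_flags(report)
  df$converged <- fl[["converged"]]
  df$significant <- fl[["significant"]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
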