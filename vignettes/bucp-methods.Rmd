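---
title: "The BUCP model for single-case AB designs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The BUCP model for single-case AB designs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A single-case AB design observes one participant repeatedly — here, weekly
caregiver ratings on the ABC Dementia Scale (ABC-DS) — through a
non-intervention phase (A) and an intervention phase (B). The question is
whether the outcome's *level* shifted, and when. Visual inspection is the
traditional answer; the Bayesian unknown change-point (BUCP) model gives a
statistical one: it treats the timepoint at which the level shifts as an
estimated parameter rather than assuming the shift happened exactly at
intervention onset.

## The model

For observations $y_t$, $t = 0, \dots, n-1$ (0-based week index):

$$y_t = \mu_t + e_t, \qquad
  \mu_t = \begin{cases} \beta_{11} & t < CP \\ \beta_{21} & t \ge CP \end{cases}$$

with stationary AR(1) errors: $e_t = \rho\, e_{t-1} + \varepsilon_t$,
$\varepsilon_t \sim \mathcal N(0, \sigma^2)$, and
$e_0 \sim \mathcal N(0, \sigma^2/(1-\rho^2))$. The change point $CP$ is
**discrete** — the index of the first observation at the phase-B level —
matching the weekly sampling; its posterior *mean* is still generally
non-integer because it averages over the discrete posterior. The likelihood
is the exact stationary AR(1) density (the first residual uses the
stationary variance); `log_likelihood(conditional = TRUE)` provides the
condition-on-first-observation variant for sensitivity checks. The
admissible $CP$ values leave at least three observations in each phase
(`cp_support()`), the model's usual applicability rule; `ab_series()`
enforces the same rule on the designed onset.

The effect size is computed per posterior draw,

$$es = \frac{\beta_{21} - \beta_{11}}{\sigma},$$

and summarized as a posterior distribution. Two conventions deserve note.
*Sign:* standardized-difference formulas are sometimes printed as
$(\beta_{11}-\beta_{21})/\sigma_\beta$ while improvements are reported as
positive; this package fixes improvement-positive ($\beta_{21}$ above
$\beta_{11}$ is positive on scales where higher = milder), and every report
carries a footnote saying so. *Denominator:* $\sigma$ is the residual-SD
draw, divided per draw (mean of ratios, not ratio of posterior means), so
the es summary is a genuine posterior functional.

## Priors

Published BUCP case analyses rarely state their priors, so these are the
package's own choices, all recorded in the report for audit:

| parameter | prior | default | why |
|---|---|---|---|
| $\beta_{11}, \beta_{21}$ | Normal$(m_0, s_0^2)$ | $m_0 = \bar y$, $s_0 = 10\,\mathrm{sd}(y)$ | weakly informative on the outcome's own scale |
| $\sigma$ | Uniform$(0, u)$ | $u = 5\,\mathrm{sd}(y)$ | score units; generous upper bound |
| $\rho$ | Normal$(0, 0.3^2)$ truncated to $(-1,1)$ | scale 0.3 | see below |
| $CP$ | discrete uniform | over `cp_support(n)` | no preference among admissible weeks |

**Why $\rho$ is shrunk.** An 18-point series cannot separate a level step
from near-unit-root drift: under a flat Uniform$(-1,1)$ prior the posterior
retains real mass at $|\rho|$ near 1, where the stationary level variance
$\sigma^2/(1-\rho^2)$ explodes and the phase-intercept intervals inflate to
the point that even a 3.75-standardized-unit step fails the CI-overlap rule
roughly half the time. Published fits of this model to 18-week dementia
series report $\rho$ posteriors with SDs of 0.02–0.18 — far tighter than
the $\approx 1/\sqrt{n}$ a flat prior could deliver — so strong shrinkage
is evidently the field's working practice even when unstated. The default
scale 0.3 says $|\rho| > 0.6$ is a priori unlikely for weekly behavioral
ratings, which is mild by comparison. `rho_prior_sd = Inf` restores the
flat prior for sensitivity analysis; under it the phase intervals widen
substantially and detection of even a large step degrades, which is worth
checking before trusting any single AB series.

## Sampling

`sample_posterior()` runs a Gibbs-style sweep (compiled core):

1. $CP$: exact draw from its discrete full conditional — enumerate the
   support, normalize likelihood × prior.
2. $(\beta_{11}, \beta_{21})$: joint conjugate bivariate-normal draw under
   the whitened AR(1) regression (first row scaled by $\sqrt{1-\rho^2}$,
   later rows quasi-differenced).
3. $\sigma$, then $\rho$: random-walk Metropolis on $\log\sigma$ and
   $\operatorname{atanh}\rho$ with the appropriate Jacobians.

Step sizes adapt toward a 0.44 acceptance rate by Robbins–Monro during
burn-in only and are frozen afterwards, preserving detailed balance over
retained draws; post-burn-in acceptance outside [0.15, 0.6] triggers a
tuning warning. Chains start overdispersed (`initialize_chains()`: phase
means ± jitter, $\sigma$ at sd$(y)$ × {1, 0.5, 2, 1.5}, $\rho$ over
{0, −0.5, 0.5, 0.25}, $CP$ spread across its support). The master seed
drives everything: starts are derived from it, then per-chain substream
seeds are drawn from it, so a run is reproducible end to end.

The run-size convention "120,000 MCMC draws with 4 chains and burn-in
5,000" is read as 30,000 retained draws per chain × 4 = 120,000 total,
burn-in 5,000 per chain (`mcmc_config()` defaults); the analyses in this
repository use a reduced budget of 10,000 retained draws per chain, which
on these 18-point series keeps every PSRF well under the 1.05 criterion
(the acceptance run reports the maximum) with Monte-Carlo SEs far below
the posterior SDs. No thinning is applied; draws are stored
in full.

## Convergence and decisions

`psrf()` is the classic two-part Gelman–Rubin statistic
$\sqrt{(\frac{n-1}{n}W + \frac{B}{n})/W}$ (split-chain variant available);
convergence is declared when every parameter's PSRF, including the derived
es, is below 1.05. Two degenerate conventions: all-identical draws give 1
(a fixed parameter carries no Monte-Carlo variability), internally constant
but disagreeing chains give $\infty$.

Intervals are equal-tailed 2.5/97.5 percentiles (R type-7), not HPD —
matching the generic "95% Bayesian CI" usage; `ci95()` refuses fewer than
100 draws. The significance decision requires **both** rules: phase-A and
phase-B intercept intervals must not intersect (closed intervals — touching
endpoints count as overlap), and the es interval must exclude zero. The
decision is deliberately conservative; widening any interval can only
revoke significance, never create it.

## The synthetic generator

`simulate_series()` draws from exactly the process the model assumes —
step mean, stationary AR(1) errors, stationary start — with a known truth,
and `scenario()` packages three 18-week, onset-10 conditions:

- **responder**: levels 78 → 82.5, $\sigma$ 1.2, $\rho$ 0 — a 4.5-point
  step (standardized difference 3.75), the profile of a participant whose
  severity total improves decisively from a moderate-dementia baseline
  near 78;
- **stable_null**: level 67, $\sigma$ 3.5, $\rho$ 0 — noisy stationarity
  at the week-to-week variability seen in non-responding series;
- **drifting_null**: level 67, $\sigma$ 3.5, $\rho$ 0.3 — no effect but
  serially correlated wandering, the case a change-point analysis must not
  mistake for an effect.

Integer rounding to the instrument scale is off by default (the fitted
model is continuous-normal); `round_to_scale = TRUE` produces
integer-looking fixtures. What the generator does **not** emulate:
item-level responses, rater effects and drift, floor/ceiling compression
near the scale bounds, and any systematic trend within phases. Passing
tests therefore demonstrate correctness of the machinery under the model's
own assumptions, not robustness of the model on real caregiver-rated data.

## Validation strategy

The sampler is never trusted against itself. `enumerate_cp_posterior()`
integrates the intercepts analytically (conjugacy) and $\sigma$ by
midpoint quadrature with $\rho = 0$, giving an exact change-point
posterior; the MCMC change-point posterior must match it within
total-variation distance 0.05 on every fixture. `grid_posterior_mean()`
extends the same block-analytic construction with a $\rho$ grid and must
match the sampler's continuous-parameter means within 3 Monte-Carlo SEs
(batch means). Operating characteristics close the loop: across 20 seeded
replicates per scenario the responder fires in ≥90% with median
change-point error ≤1 week, the nulls in ≤10%.

## Numerical choices and degenerate inputs

- $\sigma$ quadrature: 400 midpoint nodes on $(0, u]$ for enumeration
  (200 for the full grid); refining the grid 2× moves means by < 0.02.
- The change-point full conditional is normalized by log-sum-exp; ties in
  the posterior mode resolve to the smallest index (`cp_mode()`).
- A flat series (zero variance) is rejected by `default_priors()` —
  priors cannot be scaled to it; with externally supplied priors the
  change-point posterior correctly reverts toward its uniform prior.
- Missing weeks are rejected at read time by default; with
  `allow_gaps = TRUE` the R-level likelihood uses the exact AR(1) skip
  (mean decay $\rho^d$, variance $\sigma^2(1-\rho^{2d})/(1-\rho^2)$). The
  compiled sampler requires complete series; gapped fits are a documented
  limitation, not a silent imputation.
- Near-noise-free series concentrate all change-point mass on one index;
  the PSRF conventions above keep the report well-defined there.

## Known limitations

One participant, 18 points: the model can say whether *this* series shifted,
not why. Level change only — no slope change, no multiple change points,
no non-normal outcome families (all deliberate non-goals). The $\rho$
shrinkage default is a judgment call, defensible for weekly behavioral
ratings but wrong for strongly autocorrelated processes; rerun with
`rho_prior_sd = Inf` (or other scales) when serial dependence is itself of
interest. Decision rules based on CI overlap are conservative and their
operating characteristics depend on the MCMC budget only weakly but on the
priors strongly, as the sensitivity numbers above show.
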