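// Gibbs/Metropolis sweep for the BUCP model on a complete weekly series.
//
// Parameterization: y_t (t = 0..n-1), mu_t = b1 for t < cp else b2;
// stationary AR(1) residuals with innovation SD sigma, autocorrelation
// rho. Per sweep: cp drawn exactly from its discrete full conditional;
// (b1, b2) by a conjugate bivariate-normal draw under the whitened AR(1)
// regression; sigma and rho by random-walk Metropolis on log / atanh
// scales with Robbins-Monro step adaptation during burn-in only. All
// randomness goes through R's RNG so set.seed() governs the chain.

#include <Rcpp.h>
using namespace Rcpp;

static double loglik(const NumericVector& y, double b1, double b2,
                     double sigma, double rho, int cp) {
  const int n = y.size();
  const double s2 = sigma * sigma;
  double e_prev = y[0] - b1;  // cp >= min_per_phase >= 1
  const double v0 = s2 / (1.0 - rho * rho);
  double ll = -0.5 * (std::log(2.0 * M_PI * v0) + e_prev * e_prev / v0);
  const double lc = -0.5 * std::log(2.0 * M_PI * s2);
  for (int t = 1; t < n; ++t) {
    const double e = y[t] - ((t < cp) ? b1 : b2);
    const double r = e - rho * e_prev;
    ll += lc - 0.5 * r * r / s2;
    e_prev = e;
  }
  return ll;
}

// Whitened sufficient statistics for the intercept regression at fixed
// (rho, cp): rows sqrt(1-rho^2)*x_0 and x_t - rho*x_{t-1}, t >= 1.
static void whiten_stats(const NumericVector& y, double rho, int cp,
                         double& xtx11, double& xtx12, double& xtx22,
                         double& xtz1, double& xtz2) {
  const int n = y.size();
  const double w0 = std::sqrt(1.0 - rho * rho);
  xtx11 = w0 * w0; xtx12 = 0.0; xtx22 = 0.0;
  xtz1 = w0 * w0 * y[0]; xtz2 = 0.0;  // t = 0 always phase A (cp >= 1)
  for (int t = 1; t < n; ++t) {
    const double a  = (t < cp) ? 1.0 : 0.0;
    const double ap = (t - 1 < cp) ? 1.0 : 0.0;
    const double xa = a - rho * ap;
    const double xb = (1.0 - a) - rho * (1.0 - ap);
    const double z  = y[t] - rho * y[t - 1];
    xtx11 += xa * xa; xtx12 += xa * xb; xtx22 += xb * xb;
    xtz1  += xa * z;  xtz2  += xb * z;
  }
}

// [[Rcpp::export]]
List bucp_gibbs_chain(NumericVector y, IntegerVector cp_support,
                      double beta_mean, double beta_sd, double sigma_upper,
                      int iterations, int burn_in,
                      double b1, double b2, double sigma, double rho, int cp,
                      double step_sigma, double step_rho,
                      bool adapt, bool fix_rho, double rho_fixed,
                      double rho_prior_sd) {
  // rho prior: truncated Normal(0, rho_prior_sd^2) on (-1,1); the
  // truncation constant cancels in the Metropolis ratio. Non-finite
  // rho_prior_sd means Uniform(-1,1) (no shrinkage term).
  const bool rho_shrink = R_finite(rho_prior_sd);
  const double rho_prec = rho_shrink ? 1.0 / (rho_prior_sd * rho_prior_sd) : 0.0;
  const int n_keep = iterations;
  const int n_total = iterations + burn_in;
  const int ncand = cp_support.size();
  const double tau2 = beta_sd * beta_sd;
  if (fix_rho) rho = rho_fixed;

  if (!R_finite(loglik(y, b1, b2, sigma, rho, cp)))
    stop("non-finite likelihood at initialization (b1=%f, b2=%f, sigma=%f, rho=%f, cp=%d)",
         b1, b2, sigma, rho, cp);

  NumericMatrix draws(n_keep, 5);
  std::vector<double> lp(ncand), pr(ncand);
  double ls_sigma = std::log(step_sigma), ls_rho = std::log(step_rho);
  int acc_sigma = 0, acc_rho = 0;

  for (int it = 0; it < n_total; ++it) {
    // -- change point: exact draw from the discrete full conditional
    double mx = R_NegInf;
    for (int k = 0; k < ncand; ++k) {
      lp[k] = loglik(y, b1, b2, sigma, rho, cp_support[k]);
      if (lp[k] > mx) mx = lp[k];
    }
    double tot = 0.0;
    for (int k = 0; k < ncand; ++k) { pr[k] = std::exp(lp[k] - mx); tot += pr[k]; }
    double u = unif_rand() * tot, cum = 0.0;
    for (int k = 0; k < ncand; ++k) {
      cum += pr[k];
      if (u <= cum) { cp = cp_support[k]; break; }
    }

    // -- intercepts: conjugate bivariate normal under the whitened model
    {
      double xtx11, xtx12, xtx22, xtz1, xtz2;
      whiten_stats(y, rho, cp, xtx11, xtx12, xtx22, xtz1, xtz2);
      const double s2 = sigma * sigma;
      const double p11 = xtx11 / s2 + 1.0 / tau2;
      const double p12 = xtx12 / s2;
      const double p22 = xtx22 / s2 + 1.0 / tau2;
      const double r1 = xtz1 / s2 + beta_mean / tau2;
      const double r2 = xtz2 / s2 + beta_mean / tau2;
      // Cholesky P = L L'
      const double l11 = std::sqrt(p11);
      const double l21 = p12 / l11;
      const double l22 = std::sqrt(p22 - l21 * l21);
      // mean: solve L (L' m) = r
      const double w1 = r1 / l11;
      const double w2 = (r2 - l21 * w1) / l22;
      const double m2 = w2 / l22;
      const double m1 = (w1 - l21 * m2) / l11;
      // draw: m + L'^{-1} z
      const double z1 = norm_rand(), z2 = norm_rand();
      const double d2 = z2 / l22;
      const double d1 = (z1 - l21 * d2) / l11;
      b1 = m1 + d1;
      b2 = m2 + d2;
    }

    // -- sigma: random-walk Metropolis on log scale, prior U(0, upper)
    {
      const double cur = loglik(y, b1, b2, sigma, rho, cp);
      const double lsig = std::log(sigma);
      const double prop = lsig + std::exp(ls_sigma) * norm_rand();
      const double sig_p = std::exp(prop);
      double la = R_NegInf;
      if (sig_p < sigma_upper) {
        // Jacobian of sigma = exp(z): + z
        la = loglik(y, b1, b2, sig_p, rho, cp) - cur + (prop - lsig);
      }
      if (std::log(unif_rand()) < la) { sigma = sig_p; if (it >= burn_in) ++acc_sigma; }
      if (adapt && it < burn_in) {
        const double a = std::min(1.0, std::exp(la));
        ls_sigma += (a - 0.44) / std::sqrt((double)(it + 1));
      }
    }

    // -- rho: random-walk Metropolis on atanh scale, prior U(-1, 1)
    if (!fix_rho) {
      const double cur = loglik(y, b1, b2, sigma, rho, cp);
      const double z = std::atanh(rho);
      const double zp = z + std::exp(ls_rho) * norm_rand();
      const double rho_p = std::tanh(zp);
      // Jacobian d rho / d z = 1 - rho^2
      const double la = loglik(y, b1, b2, sigma, rho_p, cp) - cur
        + std::log1p(-rho_p * rho_p) - std::log1p(-rho * rho)
        - 0.5 * rho_prec * (rho_p * rho_p - rho * rho);
      if (std::log(unif_rand()) < la) { rho = rho_p; if (it >= burn_in) ++acc_rho; }
      if (adapt && it < burn_in) {
        const double a = std::min(1.0, std::exp(la));
        ls_rho += (a - 0.44) / std::sqrt((double)(it + 1));
      }
    }

    if (it >= burn_in) {
      const int j = it - burn_in;
      draws(j, 0) = b1; draws(j, 1) = b2; draws(j, 2) = sigma;
      draws(j, 3) = rho; draws(j, 4) = cp;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["accept_sigma"] = (double)acc_sigma / n_keep,
    _["accept_rho"] = fix_rho ? NA_REAL : (double)acc_rho / n_keep,
    _["step_sigma"] = std::exp(ls_sigma),
    _["step_rho"] = std::exp(ls_rho));
}
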