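#include <Rcpp.h>
using namespace Rcpp;

// Log-posterior and gradient of the non-centered Horseshoe logistic
// regression (see make_horseshoe_lp in R/determinants.R for the reference
// R implementation; the two are cross-checked in the test suite).
// Parameter layout: z[p], r_local[p], log rho_local[p], r_global,
// log rho_global, beta0. X is column-major (R layout); both passes over X
// run down columns so access stays sequential.
// [[Rcpp::export]]
List horseshoe_lp_grad(NumericVector par, NumericMatrix X, NumericVector y,
                       double v, double beta0_mu, double beta0_sd) {
  const int n = X.nrow(), p = X.ncol();
  const double a_l = v / 2.0, b_l = v / 2.0, a_g = 0.5, b_g = 0.5;
  const double *xp = &X[0];

  std::vector<double> z(p), rl(p), lrho_l(p), rho_l(p), lambda(p), beta(p);
  for (int j = 0; j < p; ++j) {
    z[j] = par[j];
    rl[j] = par[p + j];
    lrho_l[j] = par[2 * p + j];
    rho_l[j] = std::exp(lrho_l[j]);
  }
  const double rg = par[3 * p], lrho_g = par[3 * p + 1], b0 = par[3 * p + 2];
  const double rho_g = std::exp(lrho_g);
  const double tau = rg * std::sqrt(rho_g);
  for (int j = 0; j < p; ++j) {
    lambda[j] = rl[j] * std::sqrt(rho_l[j]);
    beta[j] = z[j] * lambda[j] * tau;
  }

  // eta = X beta + b0, accumulated column-wise
  std::vector<double> eta(n, b0);
  for (int j = 0; j < p; ++j) {
    const double bj = beta[j];
    if (bj == 0.0) continue;
    const double *col = xp + (size_t)j * n;
    for (int i = 0; i < n; ++i) eta[i] += col[i] * bj;
  }

  // Bernoulli log-likelihood and residuals, sharing one exp per row
  double lp = 0.0, sresid = 0.0;
  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) {
    const double e = eta[i];
    const double t = std::exp(-std::fabs(e));
    const double sp = (e > 0 ? e : 0.0) + std::log1p(t);
    const double pr = (e >= 0) ? 1.0 / (1.0 + t) : t / (1.0 + t);
    lp += y[i] * e - sp;
    const double r = y[i] - pr;
    resid[i] = r;
    sresid += r;
  }

  // gbeta = X' resid, column-wise dot products
  std::vector<double> gbeta(p);
  for (int j = 0; j < p; ++j) {
    const double *col = xp + (size_t)j * n;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += col[i] * resid[i];
    gbeta[j] = acc;
  }

  NumericVector grad(3 * p + 3);
  double sum_gb_zl = 0.0, sum_gb_beta = 0.0;
  for (int j = 0; j < p; ++j) {
    lp += -0.5 * z[j] * z[j] - 0.5 * rl[j] * rl[j]
          - (a_l * lrho_l[j] + b_l / rho_l[j]);
    grad[j] = gbeta[j] * lambda[j] * tau - z[j];
    grad[p + j] = gbeta[j] * z[j] * std::sqrt(rho_l[j]) * tau - rl[j];
    grad[2 * p + j] = 0.5 * gbeta[j] * z[j] * rl[j] * std::sqrt(rho_l[j]) * tau
                      - a_l + b_l / rho_l[j];
    sum_gb_zl += gbeta[j] * z[j] * lambda[j];
    sum_gb_beta += gbeta[j] * beta[j];
  }
  lp += -0.5 * rg * rg - (a_g * lrho_g + b_g / rho_g);
  const double d0 = (b0 - beta0_mu) / beta0_sd;
  lp += -0.5 * d0 * d0;
  grad[3 * p] = sum_gb_zl * std::sqrt(rho_g) - rg;
  grad[3 * p + 1] = 0.5 * sum_gb_beta - a_g + b_g / rho_g;
  grad[3 * p + 2] = sresid - (b0 - beta0_mu) / (beta0_sd * beta0_sd);

  return List::create(Named("value") = lp, Named("grad") = grad);
}
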