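#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian sampler (Michael, Schucany & Haas 1976).
static double rinvgauss1(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) *
      std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = R::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static double sample_scaled_inv_chisq(double df, double scale_sum) {
  return scale_sum / R::rchisq(df);
}

// Single-site Gibbs update of all marker effects, maintaining the residual.
static void update_beta_ridge(const NumericMatrix &X, NumericVector &e,
                              NumericVector &beta, const NumericVector &x2,
                              double varE, const NumericVector &priorVar) {
  int n = X.nrow(), p = X.ncol();
  for (int j = 0; j < p; ++j) {
    if (x2[j] <= 0.0) { beta[j] = 0.0; continue; }
    double rhs = 0.0;
    const double *xj = &X(0, j);
    for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
    rhs += x2[j] * beta[j];
    double C = x2[j] + varE / priorVar[j];
    double mean = rhs / C;
    double sd = std::sqrt(varE / C);
    double bnew = R::rnorm(mean, sd);
    double diff = beta[j] - bnew;
    if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += xj[i] * diff;
    beta[j] = bnew;
  }
}

// [[Rcpp::export]]
List brr_gibbs(const NumericMatrix X, const NumericVector y,
               const int niter, const int burnin, const int thin,
               const double df_b, const double S_b,
               const double df_e, const double S_e,
               const double varB_init, const double varE_init,
               const bool update_varB, const bool update_varE) {
  int n = X.nrow(), p = X.ncol();
  NumericVector beta(p), x2(p), e = clone(y);
  double mu = mean(y), varB = varB_init, varE = varE_init;
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    x2[j] = s;
  }
  for (int i = 0; i < n; ++i) e[i] -= mu;
  NumericVector beta_sum(p), beta_sq(p), prior(p);
  double mu_sum = 0, varB_sum = 0, varE_sum = 0;
  int nsamp = 0;
  std::vector<double> varE_chain, varB_chain;
  for (int it = 0; it < niter; ++it) {
    // intercept
    double emean = 0.0;
    for (int i = 0; i < n; ++i) emean += e[i];
    emean /= n;
    double mu_new = R::rnorm(mu + emean, std::sqrt(varE / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    // marker effects (homogeneous prior variance)
    std::fill(prior.begin(), prior.end(), varB);
    update_beta_ridge(X, e, beta, x2, varE, prior);
    // variances
    if (update_varB) {
      double ssb = 0.0;
      for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
      varB = sample_scaled_inv_chisq(df_b + p, S_b + ssb);
    }
    if (update_varE) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      varE = sample_scaled_inv_chisq(df_e + n, S_e + sse);
    }
    if (it >= burnin && ((it - burnin) % thin == 0)) {
      ++nsamp;
      mu_sum += mu; varB_sum += varB; varE_sum += varE;
      varE_chain.push_back(varE);
      varB_chain.push_back(varB);
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        beta_sq[j] += beta[j] * beta[j];
      }
    }
  }
  NumericVector bmean(p), bsd(p);
  for (int j = 0; j < p; ++j) {
    bmean[j] = beta_sum[j] / nsamp;
    double v = beta_sq[j] / nsamp - bmean[j] * bmean[j];
    bsd[j] = std::sqrt(v > 0 ? v : 0);
  }
  return List::create(_["mu"] = mu_sum / nsamp, _["beta"] = bmean,
                      _["beta_sd"] = bsd, _["varB"] = varB_sum / nsamp,
                      _["varE"] = varE_sum / nsamp,
                      _["varE_chain"] = wrap(varE_chain),
                      _["varB_chain"] = wrap(varB_chain),
                      _["n_samples"] = nsamp);
}

// [[Rcpp::export]]
List bl_gibbs(const NumericMatrix X, const NumericVector y,
              const int niter, const int burnin, const int thin,
              const double lambda2_shape, const double lambda2_rate,
              const double df_e, const double S_e,
              const double lambda2_init, const double varE_init,
              const bool update_lambda) {
  int n = X.nrow(), p = X.ncol();
  NumericVector beta(p), x2(p), tau2(p, 1.0), prior(p), e = clone(y);
  double mu = mean(y), varE = varE_init, lambda2 = lambda2_init;
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    x2[j] = s;
  }
  for (int i = 0; i < n; ++i) e[i] -= mu;
  NumericVector beta_sum(p), beta_sq(p);
  double mu_sum = 0, varE_sum = 0, lambda2_sum = 0;
  int nsamp = 0;
  for (int it = 0; it < niter; ++it) {
    double emean = 0.0;
    for (int i = 0; i < n; ++i) emean += e[i];
    emean /= n;
    double mu_new = R::rnorm(mu + emean, std::sqrt(varE / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    // conditional prior variance of beta_j is varE * tau2_j
    for (int j = 0; j < p; ++j) prior[j] = varE * tau2[j];
    update_beta_ridge(X, e, beta, x2, varE, prior);
    // tau2 | beta, lambda2 via inverse-Gaussian on 1/tau2
    for (int j = 0; j < p; ++j) {
      double b2 = beta[j] * beta[j];
      if (b2 < 1e-14) b2 = 1e-14;
      double m = std::sqrt(lambda2 * varE / b2);
      double inv = rinvgauss1(m, lambda2);
      tau2[j] = 1.0 / inv;
    }
    if (update_lambda) {
      double st = 0.0;
      for (int j = 0; j < p; ++j) st += tau2[j];
      lambda2 = R::rgamma(lambda2_shape + p, 1.0 / (lambda2_rate + st / 2.0));
    }
    // residual variance includes the scale-mixture contribution of beta
    double sse = 0.0, ssb = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j] / tau2[j];
    varE = sample_scaled_inv_chisq(df_e + n + p, S_e + sse + ssb);
    if (it >= burnin && ((it - burnin) % thin == 0)) {
      ++nsamp;
      mu_sum += mu; varE_sum += varE; lambda2_sum += lambda2;
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        beta_sq[j] += beta[j] * beta[j];
      }
    }
  }
  NumericVector bmean(p), bsd(p);
  for (int j = 0; j < p; ++j) {
    bmean[j] = beta_sum[j] / nsamp;
    double v = beta_sq[j] / nsamp - bmean[j] * bmean[j];
    bsd[j] = std::sqrt(v > 0 ? v : 0);
  }
  return List::create(_["mu"] = mu_sum / nsamp, _["beta"] = bmean,
                      _["beta_sd"] = bsd, _["varE"] = varE_sum / nsamp,
                      _["lambda2"] = lambda2_sum / nsamp,
                      _["n_samples"] = nsamp);
}
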