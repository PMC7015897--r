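#include <Rcpp.h>
using namespace Rcpp;

// Marker-effect Gibbs samplers for whole-genome regression.
// All random draws go through R's RNG so set.seed() in R gives
// bitwise-reproducible chains.

static inline double rinvgauss1(double mu, double lambda) {
  // Michael, Schucany & Haas (1976)
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return (mu * mu) / x;
}

static inline double rscinvchisq(double df, double sum_sq) {
  // draw from scaled-inverse-chi-square given prior+data sum of squares
  return sum_sq / R::rchisq(df);
}

// [[Rcpp::export]]
List brr_gibbs_cpp(NumericMatrix X, NumericVector y,
                   int n_iter, int burn_in, int thin,
                   double df_prior, double ss_b, double ss_e,
                   double init_s2b, double init_s2e,
                   bool fixed_var) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  std::vector<double> beta(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2b = init_s2b, s2e = init_s2e;

  int n_keep = (n_iter - burn_in) / thin;
  NumericVector beta_mean(p), s2b_draws(n_keep), s2e_draws(n_keep);
  double mu_mean = 0.0;
  int keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    double em = 0.0;
    for (int i = 0; i < n; ++i) em += e[i] + mu;
    em /= n;
    double mu_new = em + norm_rand() * std::sqrt(s2e / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    // marker effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += X(i, j) * e[i];
      xe += xtx[j] * beta[j];
      double C = xtx[j] + s2e / s2b;
      double bnew = xe / C + norm_rand() * std::sqrt(s2e / C);
      double diff = beta[j] - bnew;
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * diff;
      beta[j] = bnew;
    }
    if (!fixed_var) {
      double ssb = 0.0;
      for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
      s2b = rscinvchisq(df_prior + p, ss_b + ssb);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      s2e = rscinvchisq(df_prior + n, ss_e + sse);
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      mu_mean += mu;
      for (int j = 0; j < p; ++j) beta_mean[j] += beta[j];
      s2b_draws[keep] = s2b;
      s2e_draws[keep] = s2e;
      ++keep;
    }
  }
  mu_mean /= n_keep;
  for (int j = 0; j < p; ++j) beta_mean[j] /= n_keep;
  return List::create(_["mu"] = mu_mean, _["beta"] = beta_mean,
                      _["s2b"] = s2b_draws, _["s2e"] = s2e_draws);
}

// [[Rcpp::export]]
List bl_gibbs_cpp(NumericMatrix X, NumericVector y,
                  int n_iter, int burn_in, int thin,
                  double df_prior, double ss_e,
                  double lambda2_shape, double lambda2_rate,
                  double init_s2e, double init_lambda2) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  std::vector<double> beta(p, 0.0), e(n), tau2(p, 1.0);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = init_s2e, lambda2 = init_lambda2;

  int n_keep = (n_iter - burn_in) / thin;
  NumericVector beta_mean(p), s2e_draws(n_keep), lambda2_draws(n_keep);
  double mu_mean = 0.0;
  int keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double em = 0.0;
    for (int i = 0; i < n; ++i) em += e[i] + mu;
    em /= n;
    double mu_new = em + norm_rand() * std::sqrt(s2e / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    // effects: beta_j ~ N(0, s2e * tau2_j)  (Park & Casella scale mixture)
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += X(i, j) * e[i];
      xe += xtx[j] * beta[j];
      double C = xtx[j] + 1.0 / tau2[j];
      double bnew = xe / C + norm_rand() * std::sqrt(s2e / C);
      double diff = beta[j] - bnew;
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * diff;
      beta[j] = bnew;
    }
    // mixing variances
    for (int j = 0; j < p; ++j) {
      double b2 = beta[j] * beta[j];
      if (b2 < 1e-20) b2 = 1e-20;
      double m = std::sqrt(lambda2 * s2e / b2);
      double invtau = rinvgauss1(m, lambda2);
      tau2[j] = 1.0 / invtau;
    }
    // lambda^2 | tau2 ~ Gamma(p + shape, rate = sum(tau2)/2 + rate0)
    double st = 0.0;
    for (int j = 0; j < p; ++j) st += tau2[j];
    lambda2 = R::rgamma(p + lambda2_shape, 1.0 / (st / 2.0 + lambda2_rate));
    // residual variance (beta/ tau2 term enters because prior var is s2e*tau2)
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    double ssbt = 0.0;
    for (int j = 0; j < p; ++j) ssbt += beta[j] * beta[j] / tau2[j];
    s2e = rscinvchisq(df_prior + n + p, ss_e + sse + ssbt);
    if (it > burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      mu_mean += mu;
      for (int j = 0; j < p; ++j) beta_mean[j] += beta[j];
      s2e_draws[keep] = s2e;
      lambda2_draws[keep] = lambda2;
      ++keep;
    }
  }
  mu_mean /= n_keep;
  for (int j = 0; j < p; ++j) beta_mean[j] /= n_keep;
  return List::create(_["mu"] = mu_mean, _["beta"] = beta_mean,
                      _["s2e"] = s2e_draws, _["lambda2"] = lambda2_draws);
}
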