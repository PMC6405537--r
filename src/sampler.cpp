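// Adaptive random-walk Metropolis-within-Gibbs sampler for the hierarchical
// Bernoulli detection model. The observation model is
//   y_i ~ Bernoulli(sigmoid(esp_i)),  esp_i = sum_k theta[P[i,k]] * W[i,k] + eps_i
// where P holds parameter indices per covariate block and W the multipliers
// (1 for class effects, the standardized covariate for slopes). Unit
// contributions carry hierarchical prior means: the person-level linear model
// mu = Z * gamma for humans, the sample mean m for ARUs. Scalar proposals use
// cached per-observation log-likelihood terms so each update touches only the
// observations its parameter enters.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double CLAMP = 1e-12;

static inline double ll_bern(int y, double esp) {
  double p = 1.0 / (1.0 + std::exp(-esp));
  if (p < CLAMP) p = CLAMP;
  else if (p > 1.0 - CLAMP) p = 1.0 - CLAMP;
  return y ? std::log(p) : std::log(1.0 - p);
}

// [[Rcpp::export]]
List run_chain_cpp(IntegerVector y,
                   IntegerMatrix obs_par, NumericMatrix obs_w,
                   int n_par,
                   NumericVector prior_prec, NumericVector prior_mean0,
                   IntegerVector prior_type,     // 0 fixed, 1 human unit, 2 ARU unit
                   IntegerVector human_of_par,   // 1-based row of Z for type 1
                   NumericMatrix Z,              // H x G
                   NumericVector gamma_prec,
                   IntegerVector human_unit_par, // theta index (1-based) per human
                   IntegerVector aru_unit_par,
                   double hyper_prec,
                   bool include_eps, double eps_prec,
                   int burn_in, int n_iter, int thin,
                   double init_jitter) {
  const int n = y.size();
  const int K = obs_par.ncol();
  const int H = Z.nrow();
  const int G = Z.ncol();
  const int n_aru = aru_unit_par.size();
  const bool has_aru = n_aru > 0;

  // observation lists per parameter
  std::vector<std::vector<int> > par_obs(n_par);
  std::vector<std::vector<double> > par_w(n_par);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      int j = obs_par(i, k);
      if (j > 0) { par_obs[j - 1].push_back(i); par_w[j - 1].push_back(obs_w(i, k)); }
    }
  // humans affected by each gamma component
  std::vector<std::vector<int> > gam_h(G);
  for (int g = 0; g < G; ++g)
    for (int h = 0; h < H; ++h)
      if (Z(h, g) != 0.0) gam_h[g].push_back(h);

  std::vector<double> theta(n_par), gamma(G), eps(n, 0.0);
  double m = 0.0;
  for (int j = 0; j < n_par; ++j) theta[j] = (2.0 * unif_rand() - 1.0) * init_jitter;
  for (int g = 0; g < G; ++g) gamma[g] = (2.0 * unif_rand() - 1.0) * init_jitter;
  if (has_aru) m = (2.0 * unif_rand() - 1.0) * init_jitter;
  if (include_eps)
    for (int i = 0; i < n; ++i) eps[i] = (2.0 * unif_rand() - 1.0) * init_jitter;

  std::vector<double> esp(n, 0.0), ll(n);
  for (int j = 0; j < n_par; ++j)
    for (size_t t = 0; t < par_obs[j].size(); ++t)
      esp[par_obs[j][t]] += theta[j] * par_w[j][t];
  for (int i = 0; i < n; ++i) { esp[i] += eps[i]; ll[i] = ll_bern(y[i], esp[i]); }

  std::vector<double> mu(H, 0.0);
  for (int h = 0; h < H; ++h)
    for (int g = 0; g < G; ++g) mu[h] += Z(h, g) * gamma[g];

  std::vector<double> s_theta(n_par, 0.5), s_gamma(G, 0.5);
  double s_m = 0.5, s_eps = 0.5;
  std::vector<int> acc_theta(n_par, 0), try_theta(n_par, 0);
  std::vector<int> acc_gamma(G, 0), try_gamma(G, 0);
  int acc_m = 0, try_m = 0; long acc_eps = 0, try_eps = 0;
  int batch = 0;

  const int n_keep = n_iter / thin;
  const int n_out = n_par + G + (has_aru ? 1 : 0);
  NumericMatrix draws(n_keep, n_out);
  int kept = 0;

  auto theta_prior_mean = [&](int j) -> double {
    switch (prior_type[j]) {
      case 1: return mu[human_of_par[j] - 1];
      case 2: return m;
      default: return prior_mean0[j];
    }
  };

  std::vector<double> ll_prop(n);
  const int total = burn_in + n_iter;
  for (int iter = 1; iter <= total; ++iter) {
    // covariate-class effects, slopes, unit contributions
    for (int j = 0; j < n_par; ++j) {
      double d = s_theta[j] * norm_rand();
      double pm = theta_prior_mean(j);
      double old_ = theta[j], prop = old_ + d;
      double lr = -0.5 * prior_prec[j] *
        ((prop - pm) * (prop - pm) - (old_ - pm) * (old_ - pm));
      const std::vector<int>& oi = par_obs[j];
      const std::vector<double>& ow = par_w[j];
      for (size_t t = 0; t < oi.size(); ++t) {
        ll_prop[t] = ll_bern(y[oi[t]], esp[oi[t]] + ow[t] * d);
        lr += ll_prop[t] - ll[oi[t]];
      }
      ++try_theta[j];
      if (std::log(unif_rand()) < lr) {
        theta[j] = prop;
        for (size_t t = 0; t < oi.size(); ++t) {
          esp[oi[t]] += ow[t] * d;
          ll[oi[t]] = ll_prop[t];
        }
        ++acc_theta[j];
      }
    }
    // person-level terms: likelihood is the human-contribution hierarchy
    for (int g = 0; g < G; ++g) {
      double d = s_gamma[g] * norm_rand();
      double old_ = gamma[g], prop = old_ + d;
      double lr = -0.5 * gamma_prec[g] * (prop * prop - old_ * old_);
      const std::vector<int>& hs = gam_h[g];
      for (size_t t = 0; t < hs.size(); ++t) {
        int h = hs[t];
        int jp = human_unit_par[h] - 1;
        double u = theta[jp], pp = prior_prec[jp];
        double mnew = mu[h] + Z(h, g) * d;
        lr += -0.5 * pp * ((u - mnew) * (u - mnew) - (u - mu[h]) * (u - mu[h]));
      }
      ++try_gamma[g];
      if (std::log(unif_rand()) < lr) {
        gamma[g] = prop;
        for (size_t t = 0; t < hs.size(); ++t) mu[hs[t]] += Z(hs[t], g) * d;
        ++acc_gamma[g];
      }
    }
    // ARU sample mean
    if (has_aru) {
      double d = s_m * norm_rand();
      double prop = m + d;
      double lr = -0.5 * hyper_prec * (prop * prop - m * m);
      for (int t = 0; t < n_aru; ++t) {
        int jp = aru_unit_par[t] - 1;
        double u = theta[jp], pp = prior_prec[jp];
        lr += -0.5 * pp * ((u - prop) * (u - prop) - (u - m) * (u - m));
      }
      ++try_m;
      if (std::log(unif_rand()) < lr) { m = prop; ++acc_m; }
    }
    // per-observation overdispersion
    if (include_eps) {
      for (int i = 0; i < n; ++i) {
        double d = s_eps * norm_rand();
        double old_ = eps[i], prop = old_ + d;
        double lln = ll_bern(y[i], esp[i] + d);
        double lr = -0.5 * eps_prec * (prop * prop - old_ * old_) +
          lln - ll[i];
        ++try_eps;
        if (std::log(unif_rand()) < lr) {
          eps[i] = prop; esp[i] += d; ll[i] = lln;
          ++acc_eps;
        }
      }
    }
    // Robbins-Monro scale adaptation, burn-in only (0.44 target)
    if (iter <= burn_in && iter % 50 == 0) {
      ++batch;
      double step = std::min(0.25, 1.0 / std::sqrt((double) batch));
      for (int j = 0; j < n_par; ++j) {
        double r = try_theta[j] ? (double) acc_theta[j] / try_theta[j] : 0.44;
        s_theta[j] *= std::exp(r > 0.44 ? step : -step);
        acc_theta[j] = try_theta[j] = 0;
      }
      for (int g = 0; g < G; ++g) {
        double r = try_gamma[g] ? (double) acc_gamma[g] / try_gamma[g] : 0.44;
        s_gamma[g] *= std::exp(r > 0.44 ? step : -step);
        acc_gamma[g] = try_gamma[g] = 0;
      }
      if (try_m) {
        double r = (double) acc_m / try_m;
        s_m *= std::exp(r > 0.44 ? step : -step);
        acc_m = try_m = 0;
      }
      if (try_eps) {
        double r = (double) acc_eps / try_eps;
        s_eps *= std::exp(r > 0.44 ? step : -step);
        acc_eps = try_eps = 0;
      }
    }
    if (iter > burn_in) {
      int post = iter - burn_in;
      if (post % thin == 0 && kept < n_keep) {
        for (int j = 0; j < n_par; ++j) draws(kept, j) = theta[j];
        for (int g = 0; g < G; ++g) draws(kept, n_par + g) = gamma[g];
        if (has_aru) draws(kept, n_par + G) = m;
        ++kept;
      }
    }
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  // full log posterior at the final state, for cross-checking against the
  // plain-R reference density
  double lp = 0.0;
  for (int i = 0; i < n; ++i) lp += ll[i];
  for (int j = 0; j < n_par; ++j)
    lp += R::dnorm4(theta[j], theta_prior_mean(j),
                    1.0 / std::sqrt(prior_prec[j]), 1);
  for (int g = 0; g < G; ++g)
    lp += R::dnorm4(gamma[g], 0.0, 1.0 / std::sqrt(gamma_prec[g]), 1);
  if (has_aru) lp += R::dnorm4(m, 0.0, 1.0 / std::sqrt(hyper_prec), 1);
  if (include_eps)
    for (int i = 0; i < n; ++i)
      lp += R::dnorm4(eps[i], 0.0, 1.0 / std::sqrt(eps_prec), 1);

  return List::create(
    _["draws"] = draws,
    _["theta_final"] = NumericVector(theta.begin(), theta.end()),
    _["gamma_final"] = NumericVector(gamma.begin(), gamma.end()),
    _["m_final"] = m,
    _["eps_final"] = NumericVector(eps.begin(), eps.end()),
    _["logpost_final"] = lp);
}
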