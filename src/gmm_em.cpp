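#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Univariate Gaussian-mixture EM, one run from a given initialisation.
// Supports equal-variance and free-variance component models. Returns the
// converged log-likelihood and parameters; a collapsed run (empty component
// or vanishing variance beyond the floor) is reported with ok = false so the
// caller can discard that restart.
//
static double em_core(const NumericVector& x, std::vector<double>& mu,
                      std::vector<double>& sd, std::vector<double>& w,
                      bool equal_var, double tol, int max_iter,
                      double sd_floor, bool& ok, bool& converged,
                      int& iters) {
  const int n = x.size();
  const int k = (int) mu.size();
  const double log2pi_half = 0.9189385332046727;
  std::vector<double> resp(n * k);
  std::vector<double> a(k), inv_sd(k);
  double ll = -INFINITY, ll_old = -INFINITY;
  ok = true; converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int j = 0; j < k; ++j) {
      a[j] = std::log(w[j]) - std::log(sd[j]) - log2pi_half;
      inv_sd[j] = 1.0 / sd[j];
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = -INFINITY;
      double lp[16];
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - mu[j]) * inv_sd[j];
        lp[j] = a[j] - 0.5 * z * z;
        if (lp[j] > m) m = lp[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        // components >36 log-units below the best contribute < 2e-16
        lp[j] = (lp[j] - m > -36.0) ? std::exp(lp[j] - m) : 0.0;
        s += lp[j];
      }
      for (int j = 0; j < k; ++j) resp[i * k + j] = lp[j] / s;
      ll += m + std::log(s);
    }
    if (std::isfinite(ll) && std::fabs(ll - ll_old) < tol) {
      converged = true;
      break;
    }
    ll_old = ll;
    double pooled = 0.0;
    for (int j = 0; j < k; ++j) {
      double nj = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        nj += resp[i * k + j];
        sx += resp[i * k + j] * x[i];
      }
      if (nj < 1e-8) { ok = false; break; }
      mu[j] = sx / nj;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mu[j];
        sv += resp[i * k + j] * d * d;
      }
      w[j] = nj / n;
      if (equal_var) {
        pooled += sv;
      } else {
        sd[j] = std::sqrt(std::max(sv / nj, sd_floor * sd_floor));
      }
    }
    if (!ok) break;
    if (equal_var) {
      double s = std::sqrt(std::max(pooled / n, sd_floor * sd_floor));
      for (int j = 0; j < k; ++j) sd[j] = s;
    }
  }
  iters = iter;
  return ll;
}

// Multi-restart screening for one (k, variance-model) combination: runs the
// EM from each row of init_mu at the screening tolerance and returns the
// best run's parameters (unpolished; the caller polishes the BIC winner).
//
// [[Rcpp::export]]
List gmm_em_multi(NumericVector x, NumericMatrix init_mu, double sigma0,
                  bool equal_var, double tol, int max_iter, double sd_floor) {
  const int k = init_mu.ncol();
  const int n_restarts = init_mu.nrow();
  double best_ll = -INFINITY;
  std::vector<double> best_mu, best_sd, best_w;
  bool any_ok = false, best_conv = false;
  for (int r = 0; r < n_restarts; ++r) {
    std::vector<double> mu(k), sd(k, sigma0), w(k, 1.0 / k);
    for (int j = 0; j < k; ++j) mu[j] = init_mu(r, j);
    bool ok, conv; int iters;
    double ll = em_core(x, mu, sd, w, equal_var, tol, max_iter, sd_floor,
                        ok, conv, iters);
    if (!ok || !std::isfinite(ll)) continue;
    any_ok = true;
    if (ll > best_ll) {
      best_ll = ll; best_mu = mu; best_sd = sd; best_w = w; best_conv = conv;
    }
  }
  if (!any_ok) return List::create(_["ok"] = false);
  return List::create(
    _["ok"] = true,
    _["loglik"] = best_ll,
    _["mu"] = NumericVector(best_mu.begin(), best_mu.end()),
    _["sd"] = NumericVector(best_sd.begin(), best_sd.end()),
    _["w"] = NumericVector(best_w.begin(), best_w.end()),
    _["converged"] = best_conv);
}

// [[Rcpp::export]]
List gmm_em_run(NumericVector x, NumericVector mu0, NumericVector sd0,
                NumericVector w0, bool equal_var, double tol, int max_iter,
                double sd_floor) {
  const int n = x.size();
  const int k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(k);
  for (int j = 0; j < k; ++j) sd[j] = (sd0.size() == k) ? sd0[j] : sd0[0];
  std::vector<double> w(w0.begin(), w0.end());
  NumericMatrix resp(n, k);
  const double log2pi_half = 0.9189385332046727; // log(2*pi)/2
  double ll = -INFINITY, ll_old = -INFINITY;
  bool ok = true, converged = false;
  int iter = 0;

  std::vector<double> a(k), inv_sd(k);
  for (iter = 0; iter < max_iter; ++iter) {
    // E step + log-likelihood (log-sum-exp)
    for (int j = 0; j < k; ++j) {
      a[j] = std::log(w[j]) - std::log(sd[j]) - log2pi_half;
      inv_sd[j] = 1.0 / sd[j];
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = -INFINITY;
      double lp[16];
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - mu[j]) * inv_sd[j];
        lp[j] = a[j] - 0.5 * z * z;
        if (lp[j] > m) m = lp[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        lp[j] = (lp[j] - m > -36.0) ? std::exp(lp[j] - m) : 0.0;
        s += lp[j];
      }
      for (int j = 0; j < k; ++j) resp(i, j) = lp[j] / s;
      ll += m + std::log(s);
    }
    if (std::isfinite(ll) && std::fabs(ll - ll_old) < tol) {
      converged = true;
      break;
    }
    ll_old = ll;

    // M step
    double pooled = 0.0;
    for (int j = 0; j < k; ++j) {
      double nj = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { nj += resp(i, j); sx += resp(i, j) * x[i]; }
      if (nj < 1e-8) { ok = false; break; }
      mu[j] = sx / nj;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mu[j];
        sv += resp(i, j) * d * d;
      }
      w[j] = nj / n;
      if (equal_var) {
        pooled += sv;
      } else {
        sd[j] = std::sqrt(std::max(sv / nj, sd_floor * sd_floor));
      }
    }
    if (!ok) break;
    if (equal_var) {
      double s = std::sqrt(std::max(pooled / n, sd_floor * sd_floor));
      for (int j = 0; j < k; ++j) sd[j] = s;
    }
  }

  return List::create(
    _["loglik"] = ll,
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sd"] = NumericVector(sd.begin(), sd.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["resp"] = resp,
    _["iter"] = iter,
    _["converged"] = converged,
    _["ok"] = ok);
}
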