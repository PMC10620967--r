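// EM inner loop for one-dimensional Gaussian mixtures. The loop is compiled
// because fits routinely take thousands of iterations at the 1e-8
// log-likelihood tolerance, across several restarts and candidate k.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Runs EM from the given starting point until the absolute log-likelihood
// change drops below tol or max_iter is reached. Returns collapsed = true
// (and stops early) when a component's SD falls below sd_floor or its
// effective weight vanishes; the caller restarts from elsewhere.
// [[Rcpp::export(name = ".em_run_cpp")]]
List em_run_cpp(NumericVector x, NumericVector mu0, NumericVector sigma0,
                NumericVector w0, double max_iter, double tol,
                double sd_floor) {
  const int n = x.size(), k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sigma(sigma0.begin(), sigma0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> logd(static_cast<size_t>(n) * k);
  std::vector<double> resp(static_cast<size_t>(n) * k);
  std::vector<double> trace;
  trace.reserve(1024);

  const double log2pi = std::log(2.0 * M_PI);
  double ll_old = R_NegInf, ll = R_NegInf;
  bool converged = false, collapsed = false;
  double iter = 0;

  while (iter < max_iter) {
    iter += 1;
    // E step with log-sum-exp
    for (int j = 0; j < k; ++j) {
      const double lw = std::log(w[j]) - std::log(sigma[j]) - 0.5 * log2pi;
      const double inv2s2 = 0.5 / (sigma[j] * sigma[j]);
      double* col = &logd[static_cast<size_t>(j) * n];
      for (int i = 0; i < n; ++i) {
        const double d = x[i] - mu[j];
        col[i] = lw - d * d * inv2s2;
      }
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = logd[i];
      for (int j = 1; j < k; ++j)
        mx = std::max(mx, logd[static_cast<size_t>(j) * n + i]);
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        const double t = std::exp(logd[static_cast<size_t>(j) * n + i] - mx);
        resp[static_cast<size_t>(j) * n + i] = t;
        s += t;
      }
      ll += mx + std::log(s);
      const double inv = 1.0 / s;
      for (int j = 0; j < k; ++j)
        resp[static_cast<size_t>(j) * n + i] *= inv;
    }
    trace.push_back(ll);
    if (std::isfinite(ll) && std::fabs(ll - ll_old) < tol) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M step
    for (int j = 0; j < k; ++j) {
      const double* rj = &resp[static_cast<size_t>(j) * n];
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { nk += rj[i]; sx += rj[i] * x[i]; }
      if (nk < 1e-12) { collapsed = true; break; }
      const double m = sx / nk;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d = x[i] - m;
        ss += rj[i] * d * d;
      }
      const double s = std::sqrt(ss / nk);
      if (s < sd_floor) { collapsed = true; break; }
      w[j] = nk / n;
      mu[j] = m;
      sigma[j] = s;
    }
    if (collapsed) break;
  }

  return List::create(
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sigma"] = NumericVector(sigma.begin(), sigma.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["loglik"] = ll,
    _["n_iter"] = iter,
    _["converged"] = converged,
    _["collapsed"] = collapsed,
    _["trace"] = NumericVector(trace.begin(), trace.end()));
}
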