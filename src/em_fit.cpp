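// EM for the clustered-MR mixture: K substantive Gaussian components with
// observation-specific known variances, a fixed null component at zero and
// a fixed broad junk component. Substantive components that lose all
// support are removed during fitting.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericVector theta, NumericVector sigma2, NumericVector mu0,
                double theta_bar, double junk_var, int max_iter, double tol) {
  const int J = theta.size();
  int K = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  int M = K + 2;
  std::vector<double> pi_k(M, 1.0 / M);

  const double LOG2PI = std::log(2.0 * M_PI);
  std::vector<double> log_base(J), inv2(J), log_null(J), log_junk(J);
  for (int j = 0; j < J; ++j) {
    log_base[j] = -0.5 * (LOG2PI + std::log(sigma2[j]));
    inv2[j] = 0.5 / sigma2[j];
    log_null[j] = log_base[j] - theta[j] * theta[j] * inv2[j];
    const double v = sigma2[j] + junk_var;
    const double d = theta[j] - theta_bar;
    log_junk[j] = -0.5 * (LOG2PI + std::log(v)) - d * d / (2.0 * v);
  }

  std::vector<double> trace;
  trace.reserve(max_iter);
  std::vector<double> incl(static_cast<size_t>(J) * M);
  std::vector<double> row(M);
  double ll_old = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    M = K + 2;
    incl.assign(static_cast<size_t>(J) * M, 0.0);
    std::vector<double> logpi(M);
    for (int m = 0; m < M; ++m) {
      logpi[m] = std::log(std::max(pi_k[m], 1e-300));
    }
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      double row_max = R_NegInf;
      for (int m = 0; m < M; ++m) {
        double ld;
        if (m < K) {
          const double d = theta[j] - mu[m];
          ld = log_base[j] - d * d * inv2[j];
        } else if (m == K) {
          ld = log_null[j];
        } else {
          ld = log_junk[j];
        }
        row[m] = ld + logpi[m];
        if (row[m] > row_max) row_max = row[m];
      }
      double s = 0.0;
      for (int m = 0; m < M; ++m) {
        row[m] = std::exp(row[m] - row_max);
        s += row[m];
      }
      ll += row_max + std::log(s);
      for (int m = 0; m < M; ++m) {
        incl[static_cast<size_t>(j) + static_cast<size_t>(J) * m] = row[m] / s;
      }
    }
    trace.push_back(ll);
    if (R_finite(ll_old) && ll - ll_old < tol) break;
    ll_old = ll;

    // M-step: precision-weighted means, mean responsibilities
    for (int k = 0; k < K; ++k) {
      double sw = 0.0, swt = 0.0;
      for (int j = 0; j < J; ++j) {
        const double w =
            incl[static_cast<size_t>(j) + static_cast<size_t>(J) * k] / sigma2[j];
        sw += w;
        swt += w * theta[j];
      }
      if (sw > 0) mu[k] = swt / sw;
    }
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      for (int j = 0; j < J; ++j) {
        s += incl[static_cast<size_t>(j) + static_cast<size_t>(J) * m];
      }
      pi_k[m] = s / J;
    }
    // remove substantive components without support
    std::vector<double> mu_new;
    std::vector<double> pi_new;
    bool dropped = false;
    for (int k = 0; k < K; ++k) {
      if (pi_k[k] < 1e-8) {
        dropped = true;
      } else {
        mu_new.push_back(mu[k]);
        pi_new.push_back(pi_k[k]);
      }
    }
    if (dropped) {
      pi_new.push_back(pi_k[K]);
      pi_new.push_back(pi_k[K + 1]);
      mu = mu_new;
      pi_k = pi_new;
      K = static_cast<int>(mu.size());
      ll_old = R_NegInf;
    }
    double tot = 0.0;
    for (size_t m = 0; m < pi_k.size(); ++m) tot += pi_k[m];
    for (size_t m = 0; m < pi_k.size(); ++m) pi_k[m] /= tot;
  }

  M = K + 2;
  NumericMatrix inclusion(J, M);
  for (int m = 0; m < M; ++m) {
    for (int j = 0; j < J; ++j) {
      inclusion(j, m) = incl[static_cast<size_t>(j) + static_cast<size_t>(J) * m];
    }
  }
  return List::create(
      _["k"] = K, _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["pi"] = NumericVector(pi_k.begin(), pi_k.end()),
      _["inclusion"] = inclusion, _["loglik"] = trace.back(),
      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()));
}
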