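#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

// Eq-7 style corpus log-likelihood from topic-gene pseudo-counts:
// T [lgamma(C b) - C lgamma(b)] + sum_t [ sum_c lgamma(n_tc + b) - lgamma(n_t. + C b) ]
static double loglik_counts(const std::vector<double>& nck,
                            const std::vector<double>& nk,
                            int K, int C, double beta) {
  double ll = K * (std::lgamma(C * beta) - C * std::lgamma(beta));
  for (int k = 0; k < K; ++k) {
    const double* row = &nck[(size_t)k * C];
    double s = 0.0;
    for (int c = 0; c < C; ++c) s += std::lgamma(row[c] + beta);
    ll += s - std::lgamma(nk[k] + C * beta);
  }
  return ll;
}

// Zeroth-order collapsed variational Bayes for LDA.
// doc, word: 0-based token indices; gamma_init: N x K responsibilities.
// Deterministic given gamma_init and iteration count.
// [[Rcpp::export]]
List cvb0_fit_cpp(IntegerVector doc, IntegerVector word,
                  int P, int C, int K,
                  double alpha, double beta,
                  NumericMatrix gamma_init,
                  int iterations, int trace_every,
                  double rel_tol, int patience) {
  const int N = doc.size();
  NumericMatrix gamma = clone(gamma_init);
  std::vector<double> nck((size_t)K * C, 0.0);
  std::vector<double> npk((size_t)P * K, 0.0);
  std::vector<double> nk(K, 0.0);

  for (int n = 0; n < N; ++n) {
    const int d = doc[n], w = word[n];
    for (int k = 0; k < K; ++k) {
      const double g = gamma(n, k);
      nck[(size_t)k * C + w] += g;
      npk[(size_t)d * K + k] += g;
      nk[k] += g;
    }
  }

  std::vector<int> trace_iter;
  std::vector<double> trace_ll;
  std::vector<double> prop(K);
  const double Cb = C * beta;
  bool converged = false;
  int stable = 0;
  double last_ll = NA_REAL;

  for (int it = 1; it <= iterations; ++it) {
    for (int n = 0; n < N; ++n) {
      const int d = doc[n], w = word[n];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        const double g = gamma(n, k);
        const double a = nck[(size_t)k * C + w] - g + beta;
        const double b = npk[(size_t)d * K + k] - g + alpha;
        const double c = nk[k] - g + Cb;
        const double v = a * b / c;
        prop[k] = v;
        tot += v;
      }
      if (!(tot > 0.0) || !std::isfinite(tot))
        stop("non-finite responsibilities at iteration %d, token %d", it, n + 1);
      for (int k = 0; k < K; ++k) {
        const double gnew = prop[k] / tot;
        const double diff = gnew - gamma(n, k);
        gamma(n, k) = gnew;
        nck[(size_t)k * C + w] += diff;
        npk[(size_t)d * K + k] += diff;
        nk[k] += diff;
      }
    }
    if (it % trace_every == 0 || it == iterations) {
      const double ll = loglik_counts(nck, nk, K, C, beta);
      trace_iter.push_back(it);
      trace_ll.push_back(ll);
      if (patience > 0 && R_finite(last_ll)) {
        if (std::fabs(ll - last_ll) < rel_tol * std::fabs(ll)) ++stable;
        else stable = 0;
        if (stable >= patience) { converged = true; last_ll = ll; break; }
      }
      last_ll = ll;
    }
  }

  NumericMatrix nck_m(K, C), npk_m(P, K);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c) nck_m(k, c) = nck[(size_t)k * C + c];
  for (int d = 0; d < P; ++d)
    for (int k = 0; k < K; ++k) npk_m(d, k) = npk[(size_t)d * K + k];

  return List::create(
    _["n_ck"] = nck_m, _["n_pk"] = npk_m, _["gamma"] = gamma,
    _["trace_iteration"] = trace_iter, _["trace_ll"] = trace_ll,
    _["converged"] = converged);
}

// Collapsed Gibbs sampler for LDA. z_init: 0-based initial topic per token.
// Uses a private mt19937 stream so runs are reproducible per seed.
// [[Rcpp::export]]
List gibbs_fit_cpp(IntegerVector doc, IntegerVector word,
                   int P, int C, int K,
                   double alpha, double beta,
                   IntegerVector z_init,
                   int iterations, int trace_every, int seed) {
  const int N = doc.size();
  std::vector<int> z(z_init.begin(), z_init.end());
  std::vector<double> nck((size_t)K * C, 0.0);
  std::vector<double> npk((size_t)P * K, 0.0);
  std::vector<double> nk(K, 0.0);
  for (int n = 0; n < N; ++n) {
    nck[(size_t)z[n] * C + word[n]] += 1.0;
    npk[(size_t)doc[n] * K + z[n]] += 1.0;
    nk[z[n]] += 1.0;
  }

  std::mt19937 gen((uint32_t)seed);
  const double inv_max = 1.0 / (double(std::mt19937::max()) + 1.0);
  std::vector<double> cum(K);
  std::vector<int> trace_iter;
  std::vector<double> trace_ll;
  const double Cb = C * beta;

  for (int it = 1; it <= iterations; ++it) {
    for (int n = 0; n < N; ++n) {
      const int d = doc[n], w = word[n], old = z[n];
      nck[(size_t)old * C + w] -= 1.0;
      npk[(size_t)d * K + old] -= 1.0;
      nk[old] -= 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += (nck[(size_t)k * C + w] + beta) *
               (npk[(size_t)d * K + k] + alpha) / (nk[k] + Cb);
        cum[k] = tot;
      }
      const double u = gen() * inv_max * tot;
      int knew = 0;
      while (knew < K - 1 && cum[knew] <= u) ++knew;
      z[n] = knew;
      nck[(size_t)knew * C + w] += 1.0;
      npk[(size_t)d * K + knew] += 1.0;
      nk[knew] += 1.0;
    }
    if (it % trace_every == 0 || it == iterations) {
      trace_iter.push_back(it);
      trace_ll.push_back(loglik_counts(nck, nk, K, C, beta));
    }
  }

  NumericMatrix nck_m(K, C), npk_m(P, K);
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c) nck_m(k, c) = nck[(size_t)k * C + c];
  for (int d = 0; d < P; ++d)
    for (int k = 0; k < K; ++k) npk_m(d, k) = npk[(size_t)d * K + k];

  return List::create(
    _["n_ck"] = nck_m, _["n_pk"] = npk_m,
    _["z"] = IntegerVector(z.begin(), z.end()),
    _["trace_iteration"] = trace_iter, _["trace_ll"] = trace_ll);
}
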