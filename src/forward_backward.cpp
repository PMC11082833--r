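#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward (Rabiner scaling) for a K-state HMM.
// logB: K x T emission log-densities (columns may carry a shared offset;
// it is removed per column and added back to the log-likelihood).
// Returns gamma (K x T), summed xi (K x K) and the log-likelihood.
// [[Rcpp::export]]
List forwardBackwardC(NumericMatrix logB, NumericMatrix A, NumericVector pi0) {
  const int K = logB.nrow(), T = logB.ncol();
  const double *plogB = REAL(logB);
  std::vector<double> b((size_t)K * T), offset(T), c(T);
  for (int t = 0; t < T; ++t) {
    const double *col = plogB + (size_t)K * t;
    double m = col[0];
    for (int k = 1; k < K; ++k) if (col[k] > m) m = col[k];
    offset[t] = m;
    double *bc = b.data() + (size_t)K * t;
    for (int k = 0; k < K; ++k) bc[k] = std::exp(col[k] - m);
  }
  std::vector<double> At((size_t)K * K);  // A in row-major (At[i*K+j] = A(i,j))
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) At[(size_t)i * K + j] = A(i, j);

  std::vector<double> alpha((size_t)K * T), beta((size_t)K * T);
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi0[k] * b[k]; s += alpha[k]; }
  if (s <= 0) stop("non-finite likelihood at t = 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha[k] /= s;
  for (int t = 1; t < T; ++t) {
    const double *ap = alpha.data() + (size_t)K * (t - 1);
    const double *bc = b.data() + (size_t)K * t;
    double *ac = alpha.data() + (size_t)K * t;
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += ap[i] * At[(size_t)i * K + j];
      a *= bc[j];
      ac[j] = a;
      s += a;
    }
    if (s <= 0) stop("non-finite likelihood during forward pass");
    c[t] = s;
    const double inv = 1.0 / s;
    for (int j = 0; j < K; ++j) ac[j] *= inv;
  }
  // backward
  for (int k = 0; k < K; ++k) beta[(size_t)K * (T - 1) + k] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const double *bn = b.data() + (size_t)K * (t + 1);
    const double *be = beta.data() + (size_t)K * (t + 1);
    double *bt = beta.data() + (size_t)K * t;
    const double inv = 1.0 / c[t + 1];
    for (int i = 0; i < K; ++i) {
      const double *Ai = At.data() + (size_t)i * K;
      double v = 0.0;
      for (int j = 0; j < K; ++j) v += Ai[j] * bn[j] * be[j];
      bt[i] = v * inv;
    }
  }
  // gamma and summed xi
  NumericMatrix gamma(K, T), xi(K, K);
  double *pg = REAL(gamma);
  for (int t = 0; t < T; ++t) {
    const double *ac = alpha.data() + (size_t)K * t;
    const double *bc = beta.data() + (size_t)K * t;
    double *gc = pg + (size_t)K * t;
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gc[k] = ac[k] * bc[k]; g += gc[k]; }
    const double inv = 1.0 / g;
    for (int k = 0; k < K; ++k) gc[k] *= inv;
  }
  std::vector<double> xiacc((size_t)K * K, 0.0);
  for (int t = 0; t < T - 1; ++t) {
    const double *ac = alpha.data() + (size_t)K * t;
    const double *bn = b.data() + (size_t)K * (t + 1);
    const double *be = beta.data() + (size_t)K * (t + 1);
    const double inv = 1.0 / c[t + 1];
    for (int i = 0; i < K; ++i) {
      const double ai = ac[i] * inv;
      const double *Ai = At.data() + (size_t)i * K;
      double *xr = xiacc.data() + (size_t)i * K;
      for (int j = 0; j < K; ++j) xr[j] += ai * Ai[j] * bn[j] * be[j];
    }
  }
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) xi(i, j) = xiacc[(size_t)i * K + j];
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + offset[t];
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}
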