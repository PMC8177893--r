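#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward on one contiguous segment.
// loglik: T x K expected log-likelihoods; logA: K x K log-transition;
// logpi: length-K log initial distribution.
// Returns gamma (T x K), xi_sum (K x K summed pairwise posteriors),
// and the log-evidence.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix loglik, NumericMatrix logA, NumericVector logpi) {
  const int T = loglik.nrow(), K = loglik.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  std::vector<double> cs(T);
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));

  // per-row likelihood scaling to avoid under/overflow
  std::vector<double> lmax(T);
  NumericMatrix b(T, K);
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) m = std::max(m, loglik(t, k));
    if (!R_FINITE(m)) stop("all-(-inf) likelihood row at t=%d", t + 1);
    lmax[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(loglik(t, k) - m);
  }

  double logZ = 0.0;
  // forward
  {
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha(0, k) = std::exp(logpi[k]) * b(0, k);
      c += alpha(0, k);
    }
    if (c <= 0) stop("zero forward mass at t=1");
    for (int k = 0; k < K; ++k) alpha(0, k) /= c;
    cs[0] = c;
    logZ += std::log(c) + lmax[0];
  }
  for (int t = 1; t < T; ++t) {
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * A(i, k);
      alpha(t, k) = s * b(t, k);
      c += alpha(t, k);
    }
    if (c <= 0) stop("zero forward mass at t=%d", t + 1);
    for (int k = 0; k < K; ++k) alpha(t, k) /= c;
    cs[t] = c;
    logZ += std::log(c) + lmax[t];
  }
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += A(i, k) * b(t + 1, k) * beta(t + 1, k);
      beta(t, i) = s / cs[t + 1];
    }
  }
  // gamma and summed xi
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  std::vector<double> tmp(K * K);
  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    for (int i = 0; i < K; ++i)
      for (int k = 0; k < K; ++k) {
        double v = alpha(t, i) * A(i, k) * b(t + 1, k) * beta(t + 1, k);
        tmp[i * K + k] = v;
        s += v;
      }
    for (int i = 0; i < K; ++i)
      for (int k = 0; k < K; ++k) xi(i, k) += tmp[i * K + k] / s;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["log_evidence"] = logZ);
}

// Viterbi decoding; ties broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix loglik, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = loglik.nrow(), K = loglik.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + loglik(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, k);
        if (v > best) { best = v; arg = i; }  // '>' keeps the lower index on ties
      }
      delta(t, k) = best + loglik(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based states
}
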