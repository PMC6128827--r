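#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a Gaussian-emission HMM.
// Returns the log-likelihood, per-frame posteriors gamma (T x K) and the
// summed expected transition counts xi (K x K).
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector means,
                          NumericVector sds, NumericMatrix A,
                          NumericVector pi) {
  const int T = x.size(), K = means.size();
  NumericMatrix B(T, K);
  for (int k = 0; k < K; ++k) {
    const double s = sds[k], m = means[k];
    const double c = 1.0 / (s * std::sqrt(2.0 * M_PI));
    for (int t = 0; t < T; ++t) {
      const double z = (x[t] - m) / s;
      B(t, k) = c * std::exp(-0.5 * z * z);
      if (B(t, k) < 1e-300) B(t, k) = 1e-300;
    }
  }
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector scale(T);
  double ll = 0.0;

  for (int k = 0; k < K; ++k) alpha(0, k) = pi[k] * B(0, k);
  double s0 = 0.0;
  for (int k = 0; k < K; ++k) s0 += alpha(0, k);
  scale[0] = s0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s0;
  ll += std::log(s0);

  for (int t = 1; t < T; ++t) {
    double st = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * B(t, k);
      st += alpha(t, k);
    }
    scale[t] = st;
    for (int k = 0; k < K; ++k) alpha(t, k) /= st;
    ll += std::log(st);
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / scale[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) /
                    scale[t + 1];
      }
    }
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Most-likely state path (Viterbi), 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_path(NumericVector x, NumericVector means,
                               NumericVector sds, NumericMatrix A,
                               NumericVector pi) {
  const int T = x.size(), K = means.size();
  NumericMatrix logB(T, K);
  for (int k = 0; k < K; ++k) {
    const double s = sds[k], m = means[k];
    const double lc = -std::log(s) - 0.5 * std::log(2.0 * M_PI);
    for (int t = 0; t < T; ++t) {
      const double z = (x[t] - m) / s;
      logB(t, k) = lc - 0.5 * z * z;
    }
  }
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = std::log(std::max(A(j, k), 1e-300));

  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(std::max(pi[k], 1e-300)) + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        const double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
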