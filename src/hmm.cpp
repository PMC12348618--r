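#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a single observation sequence.
// logB: T x K log emission densities; pi: K initial probs; A: K x K transitions.
// Rows of logB are rescaled by their maximum before exponentiation so that
// arbitrarily small densities (high-dimensional Gaussians) cannot underflow;
// the shift is added back into the log-likelihood.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logB, NumericVector pi, NumericMatrix A) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K);
  NumericVector rowmax(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    rowmax[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector c(T);
  double ll = 0.0;

  // forward pass with per-step normalisation
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("forward pass underflow at t = 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0.0) stop("forward pass underflow at t = %d", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + rowmax[t];

  // backward pass (scaled)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  // expected transition counts summed over t
  std::vector<double> tmp(K * K);
  for (int t = 0; t < T - 1; ++t) {
    double tot = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        double v = alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
        tmp[j * K + k] = v;
        tot += v;
      }
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi(j, k) += tmp[j * K + k] / tot;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Max-product (Viterbi) decoding in log space; returns a 1-based state path.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericVector logpi, NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
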