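#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward for an HMM with column-stochastic transition
// matrix P (P(alpha, beta) = prob of alpha at t given beta at t-1).
//
// logB: T x M matrix of per-bin emission log-likelihoods.
// Returns gamma (T x M), xi_sum (M x M, expected beta->alpha counts),
// log-likelihood, and optionally the full xi array ((T-1) x M x M,
// flattened) when keep_xi is true.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logB, NumericMatrix P, NumericVector init,
             bool keep_xi = false) {
  const int T = logB.nrow(), M = logB.ncol();
  NumericMatrix B(T, M);          // shifted likelihoods exp(logB - rowmax)
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int m = 1; m < M; ++m) if (logB(t, m) > mx) mx = logB(t, m);
    shift[t] = mx;
    for (int m = 0; m < M; ++m) B(t, m) = std::exp(logB(t, m) - mx);
  }

  NumericMatrix alpha(T, M), beta(T, M);
  NumericVector c(T);             // per-bin scaling constants
  // forward
  double s = 0.0;
  for (int m = 0; m < M; ++m) { alpha(0, m) = init[m] * B(0, m); s += alpha(0, m); }
  if (s <= 0) stop("forward pass underflow at t = 1");
  c[0] = s;
  for (int m = 0; m < M; ++m) alpha(0, m) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int a = 0; a < M; ++a) {
      double acc = 0.0;
      for (int b = 0; b < M; ++b) acc += P(a, b) * alpha(t - 1, b);
      acc *= B(t, a);
      alpha(t, a) = acc;
      s += acc;
    }
    if (s <= 0) stop("forward pass underflow");
    c[t] = s;
    for (int a = 0; a < M; ++a) alpha(t, a) /= s;
  }
  // backward
  for (int m = 0; m < M; ++m) beta(T - 1, m) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int b = 0; b < M; ++b) {
      double acc = 0.0;
      for (int a = 0; a < M; ++a) acc += P(a, b) * B(t + 1, a) * beta(t + 1, a);
      beta(t, b) = acc / c[t + 1];
    }
  }

  NumericMatrix gamma(T, M);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int m = 0; m < M; ++m) { gamma(t, m) = alpha(t, m) * beta(t, m); g += gamma(t, m); }
    for (int m = 0; m < M; ++m) gamma(t, m) /= g;
  }

  NumericMatrix xi_sum(M, M);
  NumericVector xi_full(keep_xi ? (R_xlen_t)(T - 1) * M * M : 0);
  for (int t = 0; t < T - 1; ++t) {
    double tot = 0.0;
    // xi_t(a, b) = P(state t+1 = a, state t = b | data)
    for (int a = 0; a < M; ++a)
      for (int b = 0; b < M; ++b) {
        double v = alpha(t, b) * P(a, b) * B(t + 1, a) * beta(t + 1, a) / c[t + 1];
        xi_sum(a, b) += v;
        tot += v;
        if (keep_xi) xi_full[(R_xlen_t)t + (R_xlen_t)(T - 1) * (a + M * b)] = v;
      }
    (void)tot;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + shift[t];

  List out = List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                          _["loglik"] = ll);
  if (keep_xi) out["xi"] = xi_full;
  return out;
}

// Viterbi decoding in log space; ties broken toward the lower mode index.
// Returns 1-based path.
// [[Rcpp::export(name = ".viterbi_core")]]
IntegerVector viterbi_core(NumericMatrix logB, NumericMatrix logP,
                           NumericVector loginit) {
  const int T = logB.nrow(), M = logB.ncol();
  NumericMatrix delta(T, M);
  IntegerMatrix psi(T, M);
  for (int m = 0; m < M; ++m) delta(0, m) = loginit[m] + logB(0, m);
  for (int t = 1; t < T; ++t) {
    for (int a = 0; a < M; ++a) {
      double best = delta(t - 1, 0) + logP(a, 0);
      int arg = 0;
      for (int b = 1; b < M; ++b) {
        double v = delta(t - 1, b) + logP(a, b);
        if (v > best) { best = v; arg = b; }   // strict >: ties keep lower b
      }
      delta(t, a) = best + logB(t, a);
      psi(t, a) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int m = 1; m < M; ++m) if (delta(T - 1, m) > best) { best = delta(T - 1, m); arg = m; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

// Per-bin log-likelihood of a tree emission model evaluated on a raster.
//
// data: N x T 0/1 matrix. logp1/logp0: length-N marginal log-probs.
// For each edge e with endpoints (ei, ej) (0-based), ledge(e, code) holds
// log p(si, sj) - log p(si) - log p(sj) with code = 2*si + sj.
// [[Rcpp::export(name = ".tree_loglik_core")]]
NumericVector tree_loglik_core(IntegerMatrix data, NumericVector logp1,
                               NumericVector logp0, IntegerVector ei,
                               IntegerVector ej, NumericMatrix ledge) {
  const int N = data.nrow(), T = data.ncol(), E = ei.size();
  NumericVector out(T);
  for (int t = 0; t < T; ++t) {
    double acc = 0.0;
    for (int i = 0; i < N; ++i) acc += data(i, t) ? logp1[i] : logp0[i];
    for (int e = 0; e < E; ++e) {
      int code = 2 * data(ei[e], t) + data(ej[e], t);
      acc += ledge(e, code);
    }
    out[t] = acc;
  }
  return out;
}
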