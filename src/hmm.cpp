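#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion. obs is 0-based. Returns log P(O | A, B, pi).
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix A, NumericMatrix B, NumericVector pi,
                       IntegerVector obs) {
  const int n = A.nrow();
  const int T = obs.size();
  std::vector<double> alpha(n), alpha_new(n);
  double loglik = 0.0;

  double c = 0.0;
  for (int i = 0; i < n; ++i) {
    alpha[i] = pi[i] * B(i, obs[0]);
    c += alpha[i];
  }
  if (c <= 0.0) return R_NegInf;
  for (int i = 0; i < n; ++i) alpha[i] /= c;
  loglik += std::log(c);

  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += alpha[i] * A(i, j);
      alpha_new[j] = s * B(j, obs[t]);
      c += alpha_new[j];
    }
    if (c <= 0.0) return R_NegInf;
    for (int j = 0; j < n; ++j) alpha[j] = alpha_new[j] / c;
    loglik += std::log(c);
  }
  return loglik;
}

// Baum-Welch EM for a discrete-observation HMM on a single sequence,
// with scaled forward/backward passes. Returns the re-estimated
// parameters and the log-likelihood trace (one entry per iteration,
// evaluated at the iteration's starting parameters).
// [[Rcpp::export]]
List hmm_baum_welch_cpp(NumericMatrix A0, NumericMatrix B0, NumericVector pi0,
                        IntegerVector obs, double tol, int max_iter) {
  const int n = A0.nrow();
  const int m = B0.ncol();
  const int T = obs.size();

  NumericMatrix A = clone(A0), B = clone(B0);
  NumericVector pi = clone(pi0);
  std::vector<double> trace;

  NumericMatrix alpha(T, n), beta(T, n);
  std::vector<double> cvec(T);

  for (int iter = 0; iter < max_iter; ++iter) {
    // forward
    double loglik = 0.0;
    double c = 0.0;
    for (int i = 0; i < n; ++i) {
      alpha(0, i) = pi[i] * B(i, obs[0]);
      c += alpha(0, i);
    }
    if (c <= 0.0) { trace.push_back(R_NegInf); break; }
    for (int i = 0; i < n; ++i) alpha(0, i) /= c;
    cvec[0] = c;
    loglik += std::log(c);
    for (int t = 1; t < T; ++t) {
      c = 0.0;
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += alpha(t - 1, i) * A(i, j);
        alpha(t, j) = s * B(j, obs[t]);
        c += alpha(t, j);
      }
      if (c <= 0.0) { c = 1e-300; }
      for (int j = 0; j < n; ++j) alpha(t, j) /= c;
      cvec[t] = c;
      loglik += std::log(c);
    }
    trace.push_back(loglik);
    if (trace.size() >= 2 &&
        loglik - trace[trace.size() - 2] < tol &&
        loglik >= trace[trace.size() - 2] - 1e-8) {
      break;
    }

    // backward (scaled by the forward constants)
    for (int i = 0; i < n; ++i) beta(T - 1, i) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < n; ++j)
          s += A(i, j) * B(j, obs[t + 1]) * beta(t + 1, j);
        beta(t, i) = s / cvec[t + 1];
      }
    }

    // re-estimation
    NumericMatrix A_num(n, n), B_num(n, m);
    std::vector<double> A_den(n, 0.0), B_den(n, 0.0);
    std::vector<double> gamma0(n);
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < n; ++i) {
        double g = alpha(t, i) * beta(t, i);
        if (t == 0) gamma0[i] = g;
        B_num(i, obs[t]) += g;
        B_den[i] += g;
        if (t < T - 1) A_den[i] += g;
      }
    }
    for (int t = 0; t < T - 1; ++t) {
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
          A_num(i, j) += alpha(t, i) * A(i, j) * B(j, obs[t + 1]) *
                         beta(t + 1, j) / cvec[t + 1];
        }
      }
    }
    double g0 = 0.0;
    for (int i = 0; i < n; ++i) g0 += gamma0[i];
    for (int i = 0; i < n; ++i) {
      pi[i] = gamma0[i] / g0;
      for (int j = 0; j < n; ++j)
        A(i, j) = A_den[i] > 0 ? A_num(i, j) / A_den[i] : 1.0 / n;
      for (int k = 0; k < m; ++k)
        B(i, k) = B_den[i] > 0 ? B_num(i, k) / B_den[i] : 1.0 / m;
    }
  }

  return List::create(_["A"] = A, _["B"] = B, _["pi"] = pi,
                      _["loglik_trace"] = NumericVector(trace.begin(),
                                                        trace.end()));
}
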