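#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo null for the transition-randomness test: draws each trial's
// run sequence from the frequency-matched memoryless chain (next state ~
// phat excluding the current state), recomputes the averaged observed and
// expected transition matrices and their chi-square distance, and counts
// draws with distance >= d_actual. Uses R's RNG (seed from the caller).
// [[Rcpp::export]]
int null_chain_exceedances(NumericVector phat, IntegerVector run_counts,
                           int n_perm, double d_actual) {
  const int k = phat.size();
  const int n_trials = run_counts.size();
  std::vector<double> o_avg(k * k), e_avg(k * k);
  std::vector<int> cnt(k * k);
  std::vector<int> s;
  std::vector<double> pb(k);
  int m = 0;

  for (int b = 0; b < n_perm; ++b) {
    std::fill(o_avg.begin(), o_avg.end(), 0.0);
    std::fill(e_avg.begin(), e_avg.end(), 0.0);
    for (int tr = 0; tr < n_trials; ++tr) {
      const int n = run_counts[tr];
      s.assign(n, 0);
      // first state ~ phat
      {
        double u = unif_rand();
        double acc = 0.0;
        int j = k - 1;
        for (int i = 0; i < k; ++i) {
          acc += phat[i];
          if (u <= acc) { j = i; break; }
        }
        s[0] = j;
      }
      for (int t = 1; t < n; ++t) {
        const int prev = s[t - 1];
        double tot = 1.0 - phat[prev];
        double u = unif_rand() * tot;
        double acc = 0.0;
        int j = -1;
        for (int i = 0; i < k; ++i) {
          if (i == prev) continue;
          acc += phat[i];
          j = i;
          if (u <= acc) break;
        }
        s[t] = j;
      }
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int t = 1; t < n; ++t) cnt[s[t - 1] * k + s[t]] += 1;
      int tot_trans = n - 1;
      for (int c = 0; c < k * k; ++c)
        o_avg[c] += static_cast<double>(cnt[c]) / tot_trans;
      std::fill(pb.begin(), pb.end(), 0.0);
      for (int t = 0; t < n; ++t) pb[s[t]] += 1.0 / n;
      for (int x = 0; x < k; ++x) {
        for (int y = 0; y < k; ++y) {
          if (x == y) continue;
          e_avg[x * k + y] += pb[y] * pb[x] / (1.0 - pb[x]);
        }
      }
    }
    double d = 0.0;
    for (int x = 0; x < k; ++x) {
      for (int y = 0; y < k; ++y) {
        if (x == y) continue;
        double o = o_avg[x * k + y] / n_trials;
        double e = e_avg[x * k + y] / n_trials;
        if (o == 0.0 && e == 0.0) continue;
        if (e <= 0.0) e = std::numeric_limits<double>::min();
        d += (o - e) * (o - e) / e;
      }
    }
    if (d >= d_actual - 1e-15) ++m;
  }
  return m;
}
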