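#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multinomial histogram via conditional binomials (the rmultinom
// algorithm), visiting bins in decreasing-probability order so the draw
// loop exits as soon as all samples are allocated. cnt must be zeroed.
static inline void draw_histogram(const NumericVector& p,
                                  const IntegerVector& ord,
                                  int n, std::vector<int>& cnt) {
  const int k = p.size();
  double p_rem = 1.0;
  int n_rem = n;
  for (int j = 0; j < k && n_rem > 0; ++j) {
    const int b = ord[j];
    const double pi = p[b];
    int x;
    if (p_rem <= pi || j == k - 1) {
      x = n_rem;
    } else {
      double pr = pi / p_rem;
      if (pr > 1.0) pr = 1.0;
      x = static_cast<int>(R::rbinom(n_rem, pr));
    }
    cnt[b] = x;
    n_rem -= x;
    p_rem -= pi;
  }
}

// Two-stage simulation of all trials at one stimulus level.
// p: bin probabilities (active bins only, summing to 1); centers: their
// bin centers (degrees); pref: 0-based bin indices in argmax preference
// order (smallest |angle| first, positive before negative); ord: 0-based
// bin indices in decreasing-probability order; w1/w2: prior weight per
// bin applied when chi = 1 / chi = 2. Stage 1 bins n_early draws and
// takes theta_max = argmax, chi = 1 iff |theta_max| < chi_threshold;
// stage 2 bins a fresh n_full draws, weights them by the chi-selected
// prior, and reads out theta_map = argmax and the percept
// (coherent iff |theta_map| < percept_threshold).
// [[Rcpp::export]]
List simulate_level_cpp(NumericVector p, int n_trials, int n_early,
                        int n_full, NumericVector w1, NumericVector w2,
                        NumericVector centers, IntegerVector pref,
                        IntegerVector ord, double chi_threshold,
                        double percept_threshold) {
  const int k = p.size();
  std::vector<int> cnt(k);
  IntegerVector chi(n_trials);
  NumericVector theta_max(n_trials), theta_map(n_trials);
  LogicalVector coherent(n_trials);

  for (int t = 0; t < n_trials; ++t) {
    // stage 1: early histogram, argmax in preference order (strict >)
    std::fill(cnt.begin(), cnt.end(), 0);
    draw_histogram(p, ord, n_early, cnt);
    int best = pref[0], best_cnt = cnt[pref[0]];
    for (int j = 1; j < k; ++j) {
      const int b = pref[j];
      if (cnt[b] > best_cnt) { best_cnt = cnt[b]; best = b; }
    }
    theta_max[t] = centers[best];
    const int c = std::fabs(centers[best]) < chi_threshold ? 1 : 2;
    chi[t] = c;

    // stage 2: fresh histogram, prior-weighted argmax
    const NumericVector& w = (c == 1) ? w1 : w2;
    std::fill(cnt.begin(), cnt.end(), 0);
    draw_histogram(p, ord, n_full, cnt);
    int best2 = pref[0];
    double best_val = cnt[pref[0]] * w[pref[0]];
    for (int j = 1; j < k; ++j) {
      const int b = pref[j];
      const double v = cnt[b] * w[b];
      if (v > best_val) { best_val = v; best2 = b; }
    }
    theta_map[t] = centers[best2];
    coherent[t] = std::fabs(centers[best2]) < percept_threshold;
  }
  return List::create(_["chi"] = chi, _["theta_max"] = theta_max,
                      _["theta_map"] = theta_map, _["coherent"] = coherent);
}

// Multi-readout variant: the same trials (same stage-1 and stage-2
// histograms, hence common random numbers) are read out under m different
// prior-weight configurations. W1/W2 are k x m matrices: column j holds
// the weights applied when chi = 1 / chi = 2 under configuration j.
// Returns the number of coherent percepts per configuration.
// [[Rcpp::export]]
IntegerVector simulate_level_multi_cpp(NumericVector p, int n_trials,
                                       int n_early, int n_full,
                                       NumericMatrix W1, NumericMatrix W2,
                                       NumericVector centers,
                                       IntegerVector pref, IntegerVector ord,
                                       double chi_threshold,
                                       double percept_threshold) {
  const int k = p.size();
  const int m = W1.ncol();
  std::vector<int> cnt(k);
  IntegerVector n_coherent(m);

  for (int t = 0; t < n_trials; ++t) {
    std::fill(cnt.begin(), cnt.end(), 0);
    draw_histogram(p, ord, n_early, cnt);
    int best = pref[0], best_cnt = cnt[pref[0]];
    for (int j = 1; j < k; ++j) {
      const int b = pref[j];
      if (cnt[b] > best_cnt) { best_cnt = cnt[b]; best = b; }
    }
    const int c = std::fabs(centers[best]) < chi_threshold ? 1 : 2;

    std::fill(cnt.begin(), cnt.end(), 0);
    draw_histogram(p, ord, n_full, cnt);
    const NumericMatrix& W = (c == 1) ? W1 : W2;
    for (int cfg = 0; cfg < m; ++cfg) {
      int best2 = pref[0];
      double best_val = cnt[pref[0]] * W(pref[0], cfg);
      for (int j = 1; j < k; ++j) {
        const int b = pref[j];
        const double v = cnt[b] * W(b, cfg);
        if (v > best_val) { best_val = v; best2 = b; }
      }
      if (std::fabs(centers[best2]) < percept_threshold) n_coherent[cfg]++;
    }
  }
  return n_coherent;
}
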