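#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Inhomogeneous Bernoulli spiking at 1-ms bins.  Per-bin spike probability of
// neuron i is clip(p_background + stimulus gain + sum of lagged coupling
// terms, 0, 1); the coupling term of edge e is w[e] when its source spiked
// delay[e] bins earlier (w carries the sign).  The stimulus gain during a
// trial of barrel b at within-trial offset tau is gain_nb(i, b) *
// profile[tau], so receptive-field overlap between barrels is expressed by
// off-"diagonal" entries of gain_nb.  Trials must be non-overlapping and
// sorted by onset.  Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List simulate_engine(int n, int T,
                     IntegerVector e_pre,      // 0-based source
                     IntegerVector e_post,     // 0-based target
                     IntegerVector e_delay,    // bins, >= 1
                     NumericVector e_w,        // signed per-bin probability
                     NumericVector p_bg,       // per-neuron background prob/bin
                     NumericMatrix gain_nb,    // n x n_barrels gain multiplier
                     IntegerVector trial_onset,   // 0-based bin, sorted
                     IntegerVector trial_barrel,  // 1..B per trial
                     int trial_window,
                     NumericVector profile) {  // gain per bin within a trial
  const int ne = e_pre.size(), ntr = trial_onset.size();
  IntegerMatrix out(n, T);
  int *o = INTEGER(out);
  std::vector<double> drive(n);
  int cur = 0;
  long clipped_high = 0, clipped_low = 0;
  for (int t = 0; t < T; ++t) {
    while (cur < ntr && t >= trial_onset[cur] + trial_window) ++cur;
    const bool active = cur < ntr && t >= trial_onset[cur];
    const int tb = active ? trial_barrel[cur] - 1 : -1;
    const double gain = active ? profile[t - trial_onset[cur]] : 0.0;
    std::fill(drive.begin(), drive.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      const int d = e_delay[e];
      if (t >= d && o[e_pre[e] + (size_t)n * (t - d)])
        drive[e_post[e]] += e_w[e];
    }
    for (int i = 0; i < n; ++i) {
      double p = p_bg[i] + drive[i];
      if (active) p += gain_nb(i, tb) * gain;
      if (p > 1.0) { p = 1.0; ++clipped_high; }
      else if (p < 0.0) { p = 0.0; ++clipped_low; }
      o[i + (size_t)n * t] = (unif_rand() < p) ? 1 : 0;
    }
  }
  return List::create(_["raster"] = out,
                      _["n_clipped_high"] = (double)clipped_high,
                      _["n_clipped_low"] = (double)clipped_low);
}
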