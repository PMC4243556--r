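#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Simulated-annealing structure search for a binary dynamic Bayesian network
// with per-edge Markov lags, scored by the BDe metric under a BDeu prior
// (equivalent sample size `ess`, uniform prior structure).  The unrolled
// graph has only inter-slice edges, so any parent assignment is acyclic and
// the score decomposes over children.  Per family (child i, parents pi(i)):
//
//   score_i = sum_k [ lgamma(Z'_ik) - lgamma(Z'_ik + Z_ik)
//                     + sum_j ( lgamma(Z'_ijk + Z_ijk) - lgamma(Z'_ijk) ) ]
//
// with Z'_ijk = ess / (2 * 2^{|pi(i)|}).  Counts run over bins
// t = Lmax(pi(i)) .. T-1 (0-based), i.e. bins whose every lagged parent
// value lies inside the dataset.
//
// Each child keeps a per-bin parent-configuration code; every parent owns a
// fixed bit slot, so adding/removing a parent is a single O(T) pass and a
// proposal is evaluated in O(T) without mutating state.
//
// Uses R's RNG throughout (seed with set.seed() in R for determinism).

namespace {

const int MAXP = 10;            // hard ceiling on parent slots per child
const int MAXK = 1 << MAXP;

struct Family {
  std::vector<int> pre, lag, slot;   // parallel arrays, one entry per parent
  std::vector<int> code;             // length T; bit s set iff parent in slot
                                     // s spiked lag_s bins before t
  bool slot_used[MAXP];
  int lmax;                          // max parent lag (0 if no parents)
  double score;
};

struct Engine {
  const int *r;                 // raster, T x n column-major: r[t + T*i]
  const int *mask;              // length T; 1 = bin excluded from scoring
  int T, n, max_parents;
  double ess;
  std::vector<int> lag_set;
  std::vector<Family> fam;
  std::vector<int> edge_lag;    // n*n; edge_lag[i*n+j] = lag of i->j, 0 none
  std::vector<int> epre, epost, elag;  // current edge list
  double total;
  int cnt0[MAXK], cnt1[MAXK];

  inline int R_(int t, int i) const { return r[t + (size_t)T * i]; }

  double score_counts(int K, int np) const {
    const double zp_jk = ess / (2.0 * std::ldexp(1.0, np));
    const double zp_k = 2.0 * zp_jk;
    const double lg_jk = R::lgammafn(zp_jk), lg_k = R::lgammafn(zp_k);
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      const int z0 = cnt0[k], z1 = cnt1[k], zk = z0 + z1;
      if (!zk) continue;
      s += lg_k - R::lgammafn(zp_k + zk);
      if (z0) s += R::lgammafn(zp_jk + z0) - lg_jk;
      if (z1) s += R::lgammafn(zp_jk + z1) - lg_jk;
    }
    return s;
  }

  // Family score of child j with an optional extra parent (add_pre >= 0)
  // and/or one parent excluded (rm_idx >= 0).  Does not mutate state.
  double eval_family(int j, int add_pre, int add_lag, int add_slot,
                     int rm_idx) {
    Family &f = fam[j];
    int np = (int)f.pre.size() + (add_pre >= 0) - (rm_idx >= 0);
    int lmax = 0, hi = -1;
    for (size_t m = 0; m < f.pre.size(); ++m) {
      if ((int)m == rm_idx) continue;
      if (f.lag[m] > lmax) lmax = f.lag[m];
      if (f.slot[m] > hi) hi = f.slot[m];
    }
    if (add_pre >= 0) {
      if (add_lag > lmax) lmax = add_lag;
      if (add_slot > hi) hi = add_slot;
    }
    const int K = 1 << (hi + 1);
    std::memset(cnt0, 0, sizeof(int) * K);
    std::memset(cnt1, 0, sizeof(int) * K);
    int rm_pre = 0, rm_lag = 0, rm_slot = 0;
    if (rm_idx >= 0) {
      rm_pre = f.pre[rm_idx]; rm_lag = f.lag[rm_idx]; rm_slot = f.slot[rm_idx];
    }
    const int *code = f.code.data();
    for (int t = lmax; t < T; ++t) {
      if (mask[t]) continue;
      int k = code[t];
      if (rm_idx >= 0 && t >= rm_lag) k -= R_(t - rm_lag, rm_pre) << rm_slot;
      if (add_pre >= 0) k += R_(t - add_lag, add_pre) << add_slot;
      if (R_(t, j)) ++cnt1[k]; else ++cnt0[k];
    }
    return score_counts(K, np);
  }

  int free_slot(int j) const {
    for (int s = 0; s < MAXP; ++s) if (!fam[j].slot_used[s]) return s;
    return -1;
  }

  void commit_add(int i, int j, int lag, int slot, double new_score) {
    Family &f = fam[j];
    f.slot_used[slot] = true;
    f.pre.push_back(i); f.lag.push_back(lag); f.slot.push_back(slot);
    for (int t = lag; t < T; ++t) f.code[t] += R_(t - lag, i) << slot;
    if (lag > f.lmax) f.lmax = lag;
    edge_lag[(size_t)i * n + j] = lag;
    epre.push_back(i); epost.push_back(j); elag.push_back(lag);
    total += new_score - f.score;
    f.score = new_score;
  }

  void commit_delete(int i, int j, double new_score) {
    Family &f = fam[j];
    int idx = -1;
    for (size_t m = 0; m < f.pre.size(); ++m)
      if (f.pre[m] == i) { idx = (int)m; break; }
    const int lag = f.lag[idx], slot = f.slot[idx];
    for (int t = lag; t < T; ++t) f.code[t] -= R_(t - lag, i) << slot;
    f.slot_used[slot] = false;
    f.pre[idx] = f.pre.back(); f.pre.pop_back();
    f.lag[idx] = f.lag.back(); f.lag.pop_back();
    f.slot[idx] = f.slot.back(); f.slot.pop_back();
    f.lmax = 0;
    for (size_t m = 0; m < f.lag.size(); ++m)
      if (f.lag[m] > f.lmax) f.lmax = f.lag[m];
    edge_lag[(size_t)i * n + j] = 0;
    for (size_t e = 0; e < epre.size(); ++e)
      if (epre[e] == i && epost[e] == j) {
        epre[e] = epre.back(); epre.pop_back();
        epost[e] = epost.back(); epost.pop_back();
        elag[e] = elag.back(); elag.pop_back();
        break;
      }
    total += new_score - f.score;
    f.score = new_score;
  }

  void reset(bool random_init, double init_density) {
    fam.assign(n, Family());
    for (int j = 0; j < n; ++j) {
      fam[j].code.assign(T, 0);
      std::memset(fam[j].slot_used, 0, sizeof(fam[j].slot_used));
      fam[j].lmax = 0;
      fam[j].score = 0.0;
    }
    edge_lag.assign((size_t)n * n, 0);
    epre.clear(); epost.clear(); elag.clear();
    total = 0.0;
    for (int j = 0; j < n; ++j) {
      fam[j].score = eval_family(j, -1, 0, 0, -1);
      total += fam[j].score;
    }
    if (random_init) {
      const int nl = (int)lag_set.size();
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
          if (i == j || (int)fam[j].pre.size() >= max_parents) continue;
          if (unif_rand() >= init_density) continue;
          const int lag = lag_set[(int)(unif_rand() * nl) % nl];
          const int slot = free_slot(j);
          const double ns = eval_family(j, i, lag, slot, -1);
          commit_add(i, j, lag, slot, ns);
        }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List anneal_engine(IntegerMatrix raster_tn, IntegerVector lag_set,
                   int max_parents, double ess, double t0, double cooling,
                   int iterations, int restarts, bool random_init,
                   double init_density, int trace_every,
                   IntegerVector bin_mask) {
  Engine eng;
  eng.r = INTEGER(raster_tn);
  eng.mask = INTEGER(bin_mask);
  eng.T = raster_tn.nrow();
  eng.n = raster_tn.ncol();
  eng.max_parents = max_parents;
  eng.ess = ess;
  eng.lag_set = as<std::vector<int>>(lag_set);
  const int n = eng.n, nl = (int)eng.lag_set.size();

  double best_score = R_NegInf;
  std::vector<int> bpre, bpost, blag;
  long accepted = 0;
  std::vector<double> tr_it, tr_temp, tr_score, tr_acc;

  for (int rep = 0; rep < restarts; ++rep) {
    eng.reset(random_init, init_density);
    if (eng.total > best_score) {
      best_score = eng.total;
      bpre = eng.epre; bpost = eng.epost; blag = eng.elag;
    }
    double temp = t0;
    for (int it = 0; it < iterations; ++it, temp *= cooling) {
      // uniform proposal over legal add/delete/reverse moves via rejection
      int mv = -1, mi = 0, mj = 0, mlag = 0, medge = 0;
      const int n_add = n * (n - 1) * nl;
      for (int attempt = 0; attempt < 10000; ++attempt) {
        const int E = (int)eng.epre.size();
        const long total_raw = (long)n_add + 2L * E;
        long idx = (long)(unif_rand() * total_raw);
        if (idx >= total_raw) idx = total_raw - 1;
        if (idx < n_add) {
          const int pair = (int)(idx / nl), lv = (int)(idx % nl);
          const int i = pair / (n - 1), jr = pair % (n - 1);
          const int j = jr + (jr >= i);
          if (eng.edge_lag[(size_t)i * n + j] ||
              (int)eng.fam[j].pre.size() >= max_parents) continue;
          mv = 0; mi = i; mj = j; mlag = eng.lag_set[lv];
        } else if (idx < n_add + E) {
          medge = (int)(idx - n_add);
          mv = 1; mi = eng.epre[medge]; mj = eng.epost[medge];
          mlag = eng.elag[medge];
        } else {
          medge = (int)(idx - n_add - E);
          const int i = eng.epre[medge], j = eng.epost[medge];
          if (eng.edge_lag[(size_t)j * n + i] ||
              (int)eng.fam[i].pre.size() >= max_parents) continue;
          mv = 2; mi = i; mj = j; mlag = eng.elag[medge];
        }
        break;
      }
      if (mv < 0) continue;   // no legal move found

      double delta = 0.0, ns_j = 0.0, ns_i = 0.0;
      int slot_j = -1, slot_i = -1;
      if (mv == 0) {
        slot_j = eng.free_slot(mj);
        ns_j = eng.eval_family(mj, mi, mlag, slot_j, -1);
        delta = ns_j - eng.fam[mj].score;
      } else if (mv == 1) {
        int idxp = -1;
        for (size_t m = 0; m < eng.fam[mj].pre.size(); ++m)
          if (eng.fam[mj].pre[m] == mi) { idxp = (int)m; break; }
        ns_j = eng.eval_family(mj, -1, 0, 0, idxp);
        delta = ns_j - eng.fam[mj].score;
      } else {
        int idxp = -1;
        for (size_t m = 0; m < eng.fam[mj].pre.size(); ++m)
          if (eng.fam[mj].pre[m] == mi) { idxp = (int)m; break; }
        ns_j = eng.eval_family(mj, -1, 0, 0, idxp);
        slot_i = eng.free_slot(mi);
        ns_i = eng.eval_family(mi, mj, mlag, slot_i, -1);
        delta = (ns_j - eng.fam[mj].score) + (ns_i - eng.fam[mi].score);
      }

      bool accept = delta >= 0.0;
      if (!accept && temp > 0.0) accept = unif_rand() < std::exp(delta / temp);
      if (accept) {
        ++accepted;
        if (mv == 0) {
          eng.commit_add(mi, mj, mlag, slot_j, ns_j);
        } else if (mv == 1) {
          eng.commit_delete(mi, mj, ns_j);
        } else {
          eng.commit_delete(mi, mj, ns_j);
          eng.commit_add(mj, mi, mlag, slot_i, ns_i);
        }
        if (eng.total > best_score + 1e-12) {
          best_score = eng.total;
          bpre = eng.epre; bpost = eng.epost; blag = eng.elag;
        }
      }
      if (trace_every > 0 && (it % trace_every) == 0) {
        tr_it.push_back(rep * (double)iterations + it);
        tr_temp.push_back(temp);
        tr_score.push_back(eng.total);
        tr_acc.push_back(accept ? 1.0 : 0.0);
      }
    }
  }

  const int E = (int)bpre.size();
  IntegerMatrix edges(E, 3);
  for (int e = 0; e < E; ++e) {
    edges(e, 0) = bpre[e] + 1;
    edges(e, 1) = bpost[e] + 1;
    edges(e, 2) = blag[e];
  }
  colnames(edges) = CharacterVector::create("pre", "post", "lag");
  List trace = R_NilValue;
  if (trace_every > 0)
    trace = List::create(_["iteration"] = tr_it, _["temperature"] = tr_temp,
                         _["score"] = tr_score, _["accepted"] = tr_acc);
  return List::create(_["edges"] = edges, _["log_score"] = best_score,
                      _["n_accepted"] = (double)accepted, _["trace"] = trace);
}
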