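#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward simulators for intracellular mtDNA drift.
//
// Two turnover models:
//   model 0 (mitotic): the pool of n molecules is doubled by n sequential
//     random replications (Polya urn: new copies immediately eligible as
//     templates) and then halved by drawing a uniform subset of n of the 2n
//     molecules.  For a two-type pool this is exactly beta-binomial doubling
//     followed by hypergeometric halving.
//   model 1 (homeostatic): n Moran replacement events per turnover; each
//     event removes one uniformly chosen molecule, then replicates one
//     uniformly chosen molecule among the n-1 survivors.
//
// All randomness goes through R's RNG, so set.seed() governs reproducibility;
// cells are simulated sequentially in index order.

// One mitotic turnover for a two-type cell: returns the new variant count.
static inline int mitotic_step_two(int k, int n) {
  if (k == 0 || k == n) return k;
  double a = R::rbeta((double)k, (double)(n - k));
  int add = (int) R::rbinom((double)n, a);
  int tot = k + add; // variant copies among 2n
  return (int) R::rhyper((double)tot, (double)(2 * n - tot), (double)n);
}

// 'events' Moran replacement events for a two-type cell.  Events that leave
// the variant count unchanged are skipped exactly: the number of no-change
// events before the next jump is Geometric(2k(n-k)/(n(n-1))), and the jump
// is +1 or -1 with equal probability.
static inline int homeostatic_events_two(int k, int n, int events) {
  long e = 0;
  while (k != 0 && k != n) {
    double q2 = 2.0 * (double)k * (double)(n - k) / ((double)n * (double)(n - 1));
    double fails = R::rgeom(q2);
    e += (long)fails + 1;
    if (e > events) break;
    k += (unif_rand() < 0.5) ? 1 : -1;
  }
  return k;
}

// [[Rcpp::export]]
List cpp_drift_two_allele(IntegerVector k0, int n, int g, int model,
                          IntegerVector record_at, int events_per_turnover) {
  int C = k0.size();
  std::vector<int> k(k0.begin(), k0.end());
  int R_ = record_at.size();
  IntegerMatrix rec(R_, C);
  IntegerVector fixed_count(g), lost_count(g);
  IntegerVector fix_time(C); // -1 = not fixed within g; 0 = fixed at start
  for (int c = 0; c < C; ++c) fix_time[c] = (k[c] == n) ? 0 : -1;
  int ri = 0;
  while (ri < R_ && record_at[ri] == 0) {
    for (int c = 0; c < C; ++c) rec(ri, c) = k[c];
    ++ri;
  }
  for (int t = 1; t <= g; ++t) {
    int nfix = 0, nlost = 0;
    for (int c = 0; c < C; ++c) {
      int kc = k[c];
      if (kc != 0 && kc != n) {
        kc = (model == 0) ? mitotic_step_two(kc, n)
                          : homeostatic_events_two(kc, n, events_per_turnover);
        k[c] = kc;
        if (kc == n && fix_time[c] < 0) fix_time[c] = t;
      }
      if (kc == n) ++nfix; else if (kc == 0) ++nlost;
    }
    fixed_count[t - 1] = nfix;
    lost_count[t - 1] = nlost;
    while (ri < R_ && record_at[ri] == t) {
      for (int c = 0; c < C; ++c) rec(ri, c) = k[c];
      ++ri;
    }
    if (t % 128 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["k_final"] = IntegerVector(k.begin(), k.end()),
                      _["fixed_count"] = fixed_count,
                      _["lost_count"] = lost_count,
                      _["fix_time"] = fix_time,
                      _["recorded"] = rec);
}

// ---------------------------------------------------------------------------
// Lineage / mutation tracking simulator.
//
// Each cell holds a forest of genotype classes.  Roots are founder molecules
// (all n initially distinct when track_founders, otherwise a single root of
// count n).  Every mutation event creates a child node carrying nmut >= 1
// new (infinite-sites) mutations on one newly replicated copy; the frequency
// of a mutation equals the subtree molecule count of the node where it
// arose, divided by n.  Parent indices always precede child indices, which
// makes subtree sums a single reverse sweep.

struct CellState {
  std::vector<int> parent; // -1 for roots
  std::vector<int> count;  // current molecule count of the class
  std::vector<int> nmut;   // number of new mutations private to this node
  int n;                   // basal copy number
};

static void subtree_sums(const CellState &cs, std::vector<long> &sub) {
  size_t m = cs.count.size();
  sub.assign(m, 0);
  for (size_t i = m; i-- > 0;) {
    sub[i] += cs.count[i];
    if (cs.parent[i] >= 0) sub[(size_t)cs.parent[i]] += sub[i];
  }
}

// drop nodes whose subtree is empty (the alive set is ancestor-closed)
static void prune(CellState &cs, const std::vector<long> &sub) {
  size_t m = cs.count.size();
  std::vector<int> remap(m, -1);
  size_t j = 0;
  for (size_t i = 0; i < m; ++i) {
    if (sub[i] > 0) {
      remap[i] = (int)j;
      cs.parent[j] = (cs.parent[i] >= 0) ? remap[(size_t)cs.parent[i]] : -1;
      cs.count[j] = cs.count[i];
      cs.nmut[j] = cs.nmut[i];
      ++j;
    }
  }
  cs.parent.resize(j);
  cs.count.resize(j);
  cs.nmut.resize(j);
}

// One mitotic turnover with mutation acquisition; lambda = r * L per
// replication event, n replication events per turnover.
static void mitotic_turnover(CellState &cs, double lambda,
                             std::vector<int> &active,
                             std::vector<int> &adds,
                             std::vector<double> &prob) {
  int n = cs.n;
  active.clear();
  for (size_t i = 0; i < cs.count.size(); ++i)
    if (cs.count[i] > 0) active.push_back((int)i);
  int m = (int)active.size();

  // doubling: Dirichlet-multinomial added counts via Gamma weights
  prob.resize((size_t)m);
  double S = 0.0;
  for (int j = 0; j < m; ++j) {
    double w = R::rgamma((double)cs.count[(size_t)active[(size_t)j]], 1.0);
    prob[(size_t)j] = w;
    S += w;
  }
  for (int j = 0; j < m; ++j) prob[(size_t)j] /= S;
  std::vector<int> out((size_t)m);
  rmultinom(n, prob.data(), m, out.data());
  adds.assign(out.begin(), out.end());

  size_t snapshot = cs.count.size(); // nodes existing before this turnover

  // mutations: every new copy independently carries Poisson(lambda) new
  // mutations, so per class the number of mutated copies is
  // Binomial(adds, 1 - exp(-lambda)) and each mutated copy carries a
  // zero-truncated Poisson count
  if (lambda > 0.0) {
    double p_mut = -std::expm1(-lambda);
    double p0 = std::exp(-lambda);
    for (int j = 0; j < m; ++j) {
      if (adds[(size_t)j] == 0) continue;
      int nm_copies = (int) R::rbinom((double)adds[(size_t)j], p_mut);
      for (int q = 0; q < nm_copies; ++q) {
        int nmut;
        if (lambda > 0.1) {
          do { nmut = (int) R::rpois(lambda); } while (nmut < 1);
        } else {
          // small lambda: quantile inversion (mutated copies are rare)
          double u = p0 + unif_rand() * (1.0 - p0);
          nmut = (int) R::qpois(u, lambda, 1, 0);
          if (nmut < 1) nmut = 1;
        }
        cs.parent.push_back(active[(size_t)j]);
        cs.count.push_back(1);
        cs.nmut.push_back(nmut);
      }
      adds[(size_t)j] -= nm_copies;
    }
  }

  // halving: multivariate hypergeometric, 2n molecules -> n retained
  long remaining = 2L * n, need = n;
  for (int j = 0; j < m; ++j) {
    size_t i = (size_t)active[(size_t)j];
    long pool = (long)cs.count[i] + (long)adds[(size_t)j];
    int take = 0;
    if (need > 0 && pool > 0)
      take = (int) R::rhyper((double)pool, (double)(remaining - pool), (double)need);
    cs.count[i] = take;
    remaining -= pool;
    need -= take;
  }
  for (size_t i = snapshot; i < cs.count.size(); ++i) {
    long pool = (long)cs.count[i];
    int take = 0;
    if (need > 0 && pool > 0)
      take = (int) R::rhyper((double)pool, (double)(remaining - pool), (double)need);
    cs.count[i] = take;
    remaining -= pool;
    need -= take;
  }
}

// categorical draw proportional to current class counts (total must be the
// current number of molecules)
static inline int pick_class(const CellState &cs, long total) {
  long x = (long)(unif_rand() * (double)total);
  long acc = 0;
  for (size_t i = 0; i < cs.count.size(); ++i) {
    acc += cs.count[i];
    if (x < acc) return (int)i;
  }
  for (size_t i = cs.count.size(); i-- > 0;)
    if (cs.count[i] > 0) return (int)i;
  return 0;
}

static void homeostatic_turnover(CellState &cs, double lambda, int events) {
  int n = cs.n;
  for (int e = 0; e < events; ++e) {
    int victim = pick_class(cs, n);
    cs.count[(size_t)victim] -= 1;
    int par = pick_class(cs, n - 1);
    int M = (lambda > 0.0) ? (int) R::rpois(lambda) : 0;
    if (M == 0) {
      cs.count[(size_t)par] += 1;
    } else {
      cs.parent.push_back(par);
      cs.count.push_back(1);
      cs.nmut.push_back(M);
    }
  }
}

// [[Rcpp::export]]
List cpp_lineage_sim(int n, int n_cells, int g, double lambda, int model,
                     IntegerVector record_at, bool track_founders,
                     bool collect_final_muts, int events_per_turnover,
                     double collect_min = 0.0) {
  int R_ = record_at.size();
  NumericMatrix founder_top(R_, n_cells), mut_top(R_, n_cells);
  NumericVector founder_top_final(n_cells), mut_top_final(n_cells);
  List final_muts(collect_final_muts ? n_cells : 0);
  std::vector<int> active, adds;
  std::vector<double> prob;
  std::vector<long> sub;

  for (int c = 0; c < n_cells; ++c) {
    CellState cs;
    cs.n = n;
    if (track_founders) {
      cs.parent.assign((size_t)n, -1);
      cs.count.assign((size_t)n, 1);
      cs.nmut.assign((size_t)n, 0);
    } else {
      cs.parent.assign(1, -1);
      cs.count.assign(1, n);
      cs.nmut.assign(1, 0);
    }
    int ri = 0;
    while (ri < R_ && record_at[ri] == 0) {
      founder_top(ri, c) = track_founders ? 1.0 / n : 1.0;
      mut_top(ri, c) = 0.0;
      ++ri;
    }
    for (int t = 1; t <= g; ++t) {
      if (model == 0) mitotic_turnover(cs, lambda, active, adds, prob);
      else homeostatic_turnover(cs, lambda, events_per_turnover);
      subtree_sums(cs, sub);
      bool rec_now = (ri < R_ && record_at[ri] == t);
      if (rec_now || t == g) {
        double ft = 0.0, mt = 0.0;
        for (size_t i = 0; i < cs.count.size(); ++i) {
          double f = (double)sub[i] / n;
          if (cs.parent[i] < 0 && f > ft) ft = f;
          if (cs.nmut[i] > 0 && f > mt) mt = f;
        }
        while (ri < R_ && record_at[ri] == t) {
          founder_top(ri, c) = ft;
          mut_top(ri, c) = mt;
          ++ri;
        }
        if (t == g) {
          founder_top_final[c] = ft;
          mut_top_final[c] = mt;
        }
      }
      prune(cs, sub);
    }
    if (collect_final_muts) {
      subtree_sums(cs, sub);
      std::vector<double> fm;
      for (size_t i = 0; i < cs.count.size(); ++i) {
        if (cs.nmut[i] > 0) {
          double f = (double)sub[i] / n;
          if (f >= collect_min)
            for (int q = 0; q < cs.nmut[i]; ++q) fm.push_back(f);
        }
      }
      final_muts[c] = NumericVector(fm.begin(), fm.end());
    }
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["founder_top"] = founder_top,
                      _["mut_top"] = mut_top,
                      _["founder_top_final"] = founder_top_final,
                      _["mut_top_final"] = mut_top_final,
                      _["final_muts"] = final_muts);
}

// Naive per-event Moran simulator on a two-type cell (validation target for
// the geometric-jump acceleration).
// [[Rcpp::export]]
IntegerVector cpp_moran_events_naive(int k, int n, int events, int reps) {
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    int kc = k;
    for (int e = 0; e < events; ++e) {
      bool victim_var = (unif_rand() * n < kc);
      int kv = kc - (victim_var ? 1 : 0);      // variants among n-1 survivors
      bool par_var = (unif_rand() * (n - 1) < kv);
      kc = kv + (par_var ? 1 : 0);
    }
    out[r] = kc;
  }
  return out;
}
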