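#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Exact branch-and-bound for budget-constrained corridor selection.
//
// mode 0 (maxPers): maximise the summed persistence of the selected
//   corridors of one species, subject to within-species independence (no two
//   selected corridors of a species share a (cell, period)) and to the cost
//   of the union of used (cell, period) units not exceeding the budget.
// mode 1 (minShortfall): minimise the summed proportional shortfalls
//   max(0, (T_s - achieved_s) / T_s) across species, same constraints;
//   cell-periods shared across species are costed once.
//
// Optimality is proved by exhausting the search tree under two admissible
// upper bounds: (i) the target-capped sum of all remaining compatible
// persistence, ignoring the budget; (ii) a fractional-knapsack bound using
// per-candidate marginal costs deflated by the across-species multiplicity
// of each cell-period (a valid lower bound on the cost any completion pays).

namespace {

struct Best {
  double value;
  double cost;
  std::vector<int> sel;
  std::vector<double> achieved;
};

struct Solver {
  int m, T, S, words_ct, words_m;
  double budget, eps;
  long long node_limit, nodes;
  bool aborted;
  int mode;
  std::vector<int> ct;        // m x T cell-period ids (flattened)
  std::vector<int> sp;        // species index per candidate
  std::vector<double> P;      // persistence per candidate
  std::vector<double> w;      // cost per cell-period id
  std::vector<double> rmult;  // across-species multiplicity per cell-period
  std::vector<double> targets;
  std::vector<std::vector<uint64_t> > conflict;  // per candidate, over candidates
  std::vector<int> order;  // branching order (density at root, desc)
  Best best;
  std::vector<int> sel;

  inline bool used_has(const std::vector<uint64_t> &used, int id) const {
    return (used[id >> 6] >> (id & 63)) & 1ULL;
  }
  inline bool alive_has(const std::vector<uint64_t> &alive, int c) const {
    return (alive[c >> 6] >> (c & 63)) & 1ULL;
  }

  double marginal_cost(const std::vector<uint64_t> &used, int c) const {
    double rc = 0;
    for (int t = 0; t < T; ++t) {
      const int id = ct[c * T + t];
      if (!used_has(used, id)) rc += w[id];
    }
    return rc;
  }

  double adjusted_cost(const std::vector<uint64_t> &used, int c) const {
    double ac = 0;
    for (int t = 0; t < T; ++t) {
      const int id = ct[c * T + t];
      if (!used_has(used, id)) ac += w[id] / rmult[id];
    }
    return ac;
  }

  // capped objective gain of adding persistence p to species s
  double gain_of(const std::vector<double> &ach, int c) const {
    if (mode == 0) return P[c];
    const int s = sp[c];
    const double before = std::min(ach[s], targets[s]);
    const double after = std::min(ach[s] + P[c], targets[s]);
    return (after - before) / targets[s];
  }

  void record(double value, double cost, const std::vector<double> &ach) {
    if (value > best.value + 1e-12) {
      best.value = value;
      best.cost = cost;
      best.sel = sel;
      best.achieved = ach;
    }
  }

  void dfs(int pos, double value, double cost,
           std::vector<double> &ach, std::vector<uint64_t> &used,
           std::vector<uint64_t> &alive) {
    if (aborted) return;
    if (++nodes > node_limit) {
      aborted = true;
      return;
    }
    record(value, cost, ach);
    while (pos < m && !alive_has(alive, order[pos])) ++pos;
    if (pos >= m) return;

    // ---- bounds over the remaining alive candidates ----
    const double cap = budget - cost;
    std::vector<std::pair<double, double> > items;  // (gain ub, adjusted cost)
    std::vector<double> remsum(mode == 1 ? S : 0, 0.0);
    double plain = 0;
    for (int k = pos; k < m; ++k) {
      const int c = order[k];
      if (!alive_has(alive, c)) continue;
      double g;
      if (mode == 0) {
        g = P[c];
        plain += g;
      } else {
        const int s = sp[c];
        remsum[s] += P[c];
        const double deficit = targets[s] - std::min(ach[s], targets[s]);
        g = std::min(P[c], deficit) / targets[s];
        if (g <= 0) continue;
      }
      items.push_back(std::make_pair(g, adjusted_cost(used, c)));
    }
    double bound_nocost = value;
    if (mode == 0) {
      bound_nocost += plain;
    } else {
      for (int s = 0; s < S; ++s) {
        const double before = std::min(ach[s], targets[s]);
        const double after = std::min(ach[s] + remsum[s], targets[s]);
        bound_nocost += (after - before) / targets[s];
      }
    }
    if (bound_nocost <= best.value + eps) return;

    std::sort(items.begin(), items.end(),
              [](const std::pair<double, double> &a,
                 const std::pair<double, double> &b) {
                return a.first * b.second > b.first * a.second;  // density desc
              });
    double knap = value, room = cap;
    for (size_t k = 0; k < items.size(); ++k) {
      const double g = items[k].first, a = items[k].second;
      if (a <= room) {
        knap += g;
        room -= a;
      } else {
        if (a > 0 && room > 0) knap += g * (room / a);
        break;
      }
    }
    if (std::min(bound_nocost, knap) <= best.value + eps) return;

    // ---- branch on the first alive candidate ----
    const int c = order[pos];
    const double rc = marginal_cost(used, c);
    const double g = gain_of(ach, c);
    if (rc <= cap + 1e-9 && (mode == 0 || g > 0)) {
      std::vector<uint64_t> used2(used);
      std::vector<uint64_t> alive2(alive);
      for (int t = 0; t < T; ++t) {
        const int id = ct[c * T + t];
        used2[id >> 6] |= (1ULL << (id & 63));
      }
      for (int wd = 0; wd < words_m; ++wd) alive2[wd] &= ~conflict[c][wd];
      alive2[c >> 6] &= ~(1ULL << (c & 63));
      ach[sp[c]] += P[c];
      sel.push_back(c);
      dfs(pos + 1, value + g, cost + rc, ach, used2, alive2);
      sel.pop_back();
      ach[sp[c]] -= P[c];
    }
    dfs(pos + 1, value, cost, ach, used, alive);
  }
};

}  // namespace

// [[Rcpp::export]]
List ccc_solve_cpp(IntegerMatrix cand_ct, IntegerVector cand_sp,
                   NumericVector cand_p, NumericVector w_ct, double budget,
                   int mode, NumericVector targets, double node_limit) {
  Solver sv;
  sv.m = cand_ct.nrow();
  sv.T = cand_ct.ncol();
  sv.S = targets.size() > 0 ? targets.size()
                            : (sv.m ? max(cand_sp) + 1 : 0);
  sv.mode = mode;
  sv.budget = budget;
  sv.eps = 1e-12;
  sv.node_limit = (long long)node_limit;
  sv.nodes = 0;
  sv.aborted = false;
  const int n_ct = w_ct.size();
  sv.words_ct = (n_ct + 63) / 64;
  sv.words_m = (sv.m + 63) / 64;
  sv.w.assign(w_ct.begin(), w_ct.end());
  sv.targets.assign(targets.begin(), targets.end());
  if (mode == 1)
    for (int s = 0; s < sv.S; ++s)
      if (sv.targets[s] <= 0) stop("minShortfall targets must be > 0");

  sv.ct.resize((size_t)sv.m * sv.T);
  sv.sp.resize(sv.m);
  sv.P.resize(sv.m);
  for (int c = 0; c < sv.m; ++c) {
    sv.sp[c] = cand_sp[c];
    sv.P[c] = cand_p[c];
    for (int t = 0; t < sv.T; ++t) {
      const int id = cand_ct(c, t);
      if (id < 0 || id >= n_ct) stop("cell-period id out of range");
      sv.ct[(size_t)c * sv.T + t] = id;
    }
  }

  // across-species multiplicity of each cell-period (>= 1 where used);
  // within a species, independence keeps multiplicity at <= 1 per solution
  sv.rmult.assign(n_ct, 0.0);
  {
    std::vector<std::vector<int> > by_ct(n_ct);
    for (int c = 0; c < sv.m; ++c)
      for (int t = 0; t < sv.T; ++t) by_ct[sv.ct[(size_t)c * sv.T + t]].push_back(c);
    std::vector<int> mark(sv.S >= 1 ? sv.S : 1, -1);
    for (int id = 0; id < n_ct; ++id) {
      int cnt = 0;
      for (size_t k = 0; k < by_ct[id].size(); ++k) {
        const int s = sv.sp[by_ct[id][k]];
        if (mark[s] != id) {
          mark[s] = id;
          ++cnt;
        }
      }
      sv.rmult[id] = cnt > 0 ? (double)cnt : 1.0;
    }
    // conflicts: same species sharing a cell-period
    sv.conflict.assign(sv.m, std::vector<uint64_t>(sv.words_m, 0ULL));
    for (int id = 0; id < n_ct; ++id) {
      const std::vector<int> &cs = by_ct[id];
      for (size_t a = 0; a < cs.size(); ++a)
        for (size_t b = a + 1; b < cs.size(); ++b)
          if (sv.sp[cs[a]] == sv.sp[cs[b]]) {
            sv.conflict[cs[a]][cs[b] >> 6] |= (1ULL << (cs[b] & 63));
            sv.conflict[cs[b]][cs[a] >> 6] |= (1ULL << (cs[a] & 63));
          }
    }
  }

  // branching order: density at the root, descending; ties by index
  std::vector<uint64_t> used0(sv.words_ct, 0ULL);
  std::vector<double> dens(sv.m);
  for (int c = 0; c < sv.m; ++c) {
    const double a = sv.adjusted_cost(used0, c);
    const double v = mode == 0 ? sv.P[c] : sv.P[c] / sv.targets[sv.sp[c]];
    dens[c] = v / (a + 1e-12);
  }
  sv.order.resize(sv.m);
  for (int c = 0; c < sv.m; ++c) sv.order[c] = c;
  std::sort(sv.order.begin(), sv.order.end(), [&](int a, int b) {
    if (dens[a] != dens[b]) return dens[a] > dens[b];
    return a < b;
  });

  sv.best.value = 0;
  sv.best.cost = 0;
  sv.best.achieved.assign(sv.S >= 1 ? sv.S : 0, 0.0);
  std::vector<double> ach(sv.S >= 1 ? sv.S : 1, 0.0);
  std::vector<uint64_t> alive(sv.words_m, 0ULL);
  for (int c = 0; c < sv.m; ++c) alive[c >> 6] |= (1ULL << (c & 63));
  if (sv.m > 0 && budget >= 0) sv.dfs(0, 0.0, 0.0, ach, used0, alive);
  if (sv.aborted) stop("branch-and-bound node limit exceeded");

  std::sort(sv.best.sel.begin(), sv.best.sel.end());
  return List::create(
      _["selected"] = IntegerVector(sv.best.sel.begin(), sv.best.sel.end()),
      _["value"] = sv.best.value, _["cost"] = sv.best.cost,
      _["achieved"] = NumericVector(sv.best.achieved.begin(),
                                    sv.best.achieved.end()),
      _["nodes"] = (double)sv.nodes);
}
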