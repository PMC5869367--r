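#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact top-K highest-persistence corridors over the time-layered DAG.
// Scores are accumulated in log space; per (cell, period) node we keep the
// K best partial paths (with predecessor pointers), so the final merge is
// exact. Ties in score are broken lexicographically by the cell sequence.

namespace {

struct Entry {
  double s;       // log persistence of the partial path
  int prev_cell;  // -1 at the first layer
  int prev_rank;
};

typedef std::vector<std::vector<std::vector<Entry> > > Layers;

// cell sequence (periods 1..t+1) of the partial path ending at layer t,
// cell j, rank r
void backtrack(const Layers &layers, int t, int j, int r, std::vector<int> &out) {
  out.resize(t + 1);
  for (int tt = t; tt >= 0; --tt) {
    out[tt] = j;
    const Entry &e = layers[tt][j][r];
    int pj = e.prev_cell, pr = e.prev_rank;
    j = pj;
    r = pr;
  }
}

// lexicographic comparison of the full prefixes; both end at layer t
bool seq_less(const Layers &layers, int t, int j1, int r1, int j2, int r2) {
  std::vector<int> a, b;
  backtrack(layers, t, j1, r1, a);
  backtrack(layers, t, j2, r2, b);
  return std::lexicographical_compare(a.begin(), a.end(), b.begin(), b.end());
}

struct Cand {
  double s;
  int prev_cell;
  int prev_rank;
};

}  // namespace

// [[Rcpp::export]]
List corridor_topk_cpp(NumericMatrix pos, IntegerVector edge_from,
                       IntegerVector edge_to, NumericVector edge_pds, int K) {
  const int n = pos.nrow();
  const int T = pos.ncol();
  if (T < 2) stop("need at least two periods");
  if (K < 1) stop("K must be >= 1");

  // log suitability; -Inf marks nonfunctional cells
  std::vector<std::vector<double> > lpos(T, std::vector<double>(n));
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i)
      lpos[t][i] = pos(i, t) > 0 ? std::log(pos(i, t)) : -INFINITY;

  // incoming adjacency with log dispersal success
  std::vector<std::vector<std::pair<int, double> > > inadj(n);
  for (int e = 0; e < edge_from.size(); ++e) {
    if (edge_pds[e] <= 0) continue;
    inadj[edge_to[e]].push_back(
        std::make_pair(edge_from[e], std::log(edge_pds[e])));
  }

  Layers layers(T);
  for (int t = 0; t < T; ++t) layers[t].resize(n);

  for (int i = 0; i < n; ++i) {
    if (std::isfinite(lpos[0][i])) {
      Entry e;
      e.s = lpos[0][i];
      e.prev_cell = -1;
      e.prev_rank = -1;
      layers[0][i].push_back(e);
    }
  }

  std::vector<Cand> cands;
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(lpos[t][j])) continue;
      cands.clear();
      for (size_t a = 0; a < inadj[j].size(); ++a) {
        const int i = inadj[j][a].first;
        const double lp = inadj[j][a].second;
        const std::vector<Entry> &prev = layers[t - 1][i];
        for (size_t r = 0; r < prev.size(); ++r) {
          Cand c;
          c.s = prev[r].s + lp + lpos[t][j];
          c.prev_cell = i;
          c.prev_rank = (int)r;
          cands.push_back(c);
        }
      }
      if (cands.empty()) continue;
      const Layers &L = layers;
      const int tp = t - 1;
      // score descending; exact ties resolved by the lexicographically
      // smallest predecessor sequence
      std::sort(cands.begin(), cands.end(),
                [&L, tp](const Cand &a, const Cand &b) {
                  if (a.s != b.s) return a.s > b.s;
                  return seq_less(L, tp, a.prev_cell, a.prev_rank,
                                  b.prev_cell, b.prev_rank);
                });
      const int keep = std::min<int>(K, (int)cands.size());
      std::vector<Entry> &node = layers[t][j];
      node.reserve(keep);
      for (int r = 0; r < keep; ++r) {
        Entry e;
        e.s = cands[r].s;
        e.prev_cell = cands[r].prev_cell;
        e.prev_rank = cands[r].prev_rank;
        node.push_back(e);
      }
    }
    Rcpp::checkUserInterrupt();
  }

  // merge the final layer
  struct Fin {
    double s;
    int cell;
    int rank;
  };
  std::vector<Fin> fin;
  for (int j = 0; j < n; ++j)
    for (size_t r = 0; r < layers[T - 1][j].size(); ++r) {
      Fin f;
      f.s = layers[T - 1][j][r].s;
      f.cell = j;
      f.rank = (int)r;
      fin.push_back(f);
    }
  const Layers &L = layers;
  const int tl = T - 1;
  std::sort(fin.begin(), fin.end(), [&L, tl](const Fin &a, const Fin &b) {
    if (a.s != b.s) return a.s > b.s;
    return seq_less(L, tl, a.cell, a.rank, b.cell, b.rank);
  });
  const int m = std::min<int>(K, (int)fin.size());

  IntegerMatrix cells(m, T);
  NumericVector logscore(m);
  std::vector<int> seq;
  for (int r = 0; r < m; ++r) {
    backtrack(layers, T - 1, fin[r].cell, fin[r].rank, seq);
    for (int t = 0; t < T; ++t) cells(r, t) = seq[t];
    logscore[r] = fin[r].s;
  }
  return List::create(_["cells"] = cells, _["logscore"] = logscore);
}
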