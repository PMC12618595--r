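// Weighted shortest-path lengths and search information on dense
// connectomes. Edge lengths are supplied by the caller (typically the
// reciprocal of the structural weight); transition probabilities for the
// search-information walker come from the raw weights. Ties between
// shortest paths are broken deterministically by preferring the path whose
// node-index sequence is lexicographically smallest, because search
// information depends on the particular path chosen.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void dijkstra_row(const NumericMatrix& L, int s,
                         std::vector<double>& dist) {
  const int n = L.nrow();
  std::vector<bool> done(n, false);
  dist.assign(n, R_PosInf);
  dist[s] = 0.0;
  for (int it = 0; it < n; ++it) {
    int u = -1;
    double best = R_PosInf;
    for (int i = 0; i < n; ++i)
      if (!done[i] && dist[i] < best) { best = dist[i]; u = i; }
    if (u < 0) break;
    done[u] = true;
    for (int v = 0; v < n; ++v) {
      double l = L(u, v);
      if (u != v && !done[v] && R_finite(l) && dist[u] + l < dist[v])
        dist[v] = dist[u] + l;
    }
  }
}

// Greedy reconstruction of the lexicographically smallest shortest path
// s -> t: at each node pick the lowest-index neighbour that can still
// complete a shortest path (certified by the distance matrix D).
static bool lex_path(const NumericMatrix& L, const NumericMatrix& D,
                     int s, int t, std::vector<int>& path) {
  const int n = L.nrow();
  path.clear();
  path.push_back(s);
  int cur = s;
  double rem = D(s, t);
  if (!R_finite(rem)) return false;
  int guard = 0;
  while (cur != t) {
    if (++guard > n) return false;
    int nxt = -1;
    for (int j = 0; j < n; ++j) {
      if (j == cur) continue;
      double l = L(cur, j);
      if (!R_finite(l)) continue;
      double tol = 1e-9 * (1.0 + std::fabs(rem));
      if (std::fabs(l + D(j, t) - rem) <= tol) { nxt = j; break; }
    }
    if (nxt < 0) return false;
    rem -= L(cur, nxt);
    path.push_back(nxt);
    cur = nxt;
  }
  return true;
}

// -log2 probability that a random walker follows `path` exactly. With
// memory, each step after the first excludes the edge just traversed from
// the walker's options.
static double path_neglog2_prob(const NumericMatrix& W,
                                const std::vector<double>& strength,
                                const std::vector<int>& path, bool memory) {
  double nl2 = 0.0;
  const double log2v = std::log(2.0);
  for (size_t m = 0; m + 1 < path.size(); ++m) {
    int u = path[m], v = path[m + 1];
    double denom = strength[u];
    if (memory && m > 0) denom -= W(u, path[m - 1]);
    nl2 -= std::log(W(u, v) / denom) / log2v;
  }
  return nl2;
}

// [[Rcpp::export]]
List spl_si_cpp(NumericMatrix W, NumericMatrix L, bool memory,
                bool return_paths) {
  const int n = W.nrow();
  if (W.ncol() != n || L.nrow() != n || L.ncol() != n)
    stop("weight and length matrices must be square and conformable");

  NumericMatrix D(n, n);
  std::vector<double> row;
  for (int s = 0; s < n; ++s) {
    dijkstra_row(L, s, row);
    for (int t = 0; t < n; ++t) D(s, t) = row[t];
  }

  std::vector<double> strength(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) strength[i] += W(i, j);

  NumericMatrix SI(n, n);
  bool connected = true;
  List paths;
  if (return_paths) paths = List(n * n);

  NumericMatrix SIdir(n, n);
  std::vector<int> path;
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < n; ++t) {
      if (s == t) continue;
      if (!R_finite(D(s, t))) {
        connected = false;
        SIdir(s, t) = NA_REAL;
        continue;
      }
      if (!lex_path(L, D, s, t, path))
        stop("shortest-path reconstruction failed for pair (%d, %d)",
             s + 1, t + 1);
      SIdir(s, t) = path_neglog2_prob(W, strength, path, memory);
      if (return_paths) {
        IntegerVector pv(path.size());
        for (size_t k = 0; k < path.size(); ++k) pv[k] = path[k] + 1;
        paths[s * n + t] = pv;
      }
    }
  }
  for (int s = 0; s < n; ++s)
    for (int t = 0; t < n; ++t)
      SI(s, t) = (s == t) ? 0.0 : 0.5 * (SIdir(s, t) + SIdir(t, s));

  List out = List::create(_["spl"] = D, _["si"] = SI,
                          _["si_directed"] = SIdir,
                          _["connected"] = connected);
  if (return_paths) out["paths"] = paths;
  return out;
}
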