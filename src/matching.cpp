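// Row-matching algorithms for correlation targeting.
//
// All three solvers take an N x N cost matrix with cost(i, j) = squared
// Euclidean distance between target row i and design row j, and return a
// 1-based permutation perm with perm[i] = the design row paired with
// target row i.

#include <Rcpp.h>
#include <limits>
#include <vector>
#include <algorithm>
#include <queue>

using namespace Rcpp;

// Exact minimum-cost assignment by the O(N^3) shortest-augmenting-path
// (Hungarian / Jonker-Volgenant family) algorithm with dual potentials.
// [[Rcpp::export(name = "lap_solve_cpp")]]
IntegerVector lap_solve_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();

  // 1-based arrays with a virtual column 0.
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }

  IntegerVector perm(n);
  for (int j = 1; j <= n; ++j) perm[p[j] - 1] = j;  // row p[j] -> column j
  return perm;
}

// Greedy matching: repeatedly pair the globally closest remaining
// (target, design) rows; ties broken by lowest target index, then lowest
// design index.
// [[Rcpp::export(name = "greedy_match_cpp")]]
IntegerVector greedy_match_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");

  struct Entry { double c; int i, j; };
  std::vector<Entry> entries;
  entries.reserve(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      entries.push_back({cost(i, j), i, j});
  std::stable_sort(entries.begin(), entries.end(),
                   [](const Entry& a, const Entry& b) {
                     if (a.c != b.c) return a.c < b.c;
                     if (a.i != b.i) return a.i < b.i;
                     return a.j < b.j;
                   });

  std::vector<bool> row_done(n, false), col_done(n, false);
  IntegerVector perm(n);
  int assigned = 0;
  for (const Entry& e : entries) {
    if (row_done[e.i] || col_done[e.j]) continue;
    perm[e.i] = e.j + 1;
    row_done[e.i] = col_done[e.j] = true;
    if (++assigned == n) break;
  }
  return perm;
}

// Stable matching by Gale-Shapley: target rows propose in order of
// increasing distance; design rows hold the closest proposal seen so far.
// [[Rcpp::export(name = "gale_shapley_cpp")]]
IntegerVector gale_shapley_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");

  // Preference lists of the proposing side (target rows).
  std::vector<std::vector<int>> pref(n, std::vector<int>(n));
  for (int i = 0; i < n; ++i) {
    std::vector<int>& pi = pref[i];
    for (int j = 0; j < n; ++j) pi[j] = j;
    std::stable_sort(pi.begin(), pi.end(), [&](int a, int b) {
      return cost(i, a) < cost(i, b);
    });
  }

  std::vector<int> next(n, 0);          // next column to propose to
  std::vector<int> holder(n, -1);       // current proposer held by column j
  std::queue<int> free_rows;
  for (int i = 0; i < n; ++i) free_rows.push(i);

  while (!free_rows.empty()) {
    int i = free_rows.front();
    free_rows.pop();
    int j = pref[i][next[i]++];
    if (holder[j] < 0) {
      holder[j] = i;
    } else if (cost(i, j) < cost(holder[j], j)) {
      free_rows.push(holder[j]);
      holder[j] = i;
    } else {
      free_rows.push(i);
    }
  }

  IntegerVector perm(n);
  for (int j = 0; j < n; ++j) perm[holder[j]] = j + 1;
  return perm;
}
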