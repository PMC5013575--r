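// Exact maximum clique by branch and bound with a greedy-colouring upper
// bound (Tomita-style, as in the MaxCliqueDyn family). Deterministic:
// vertices enter the search in degree-descending order (ties by index) and
// the incumbent is replaced only on strict improvement, so a given
// adjacency matrix always yields the same member set.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

namespace {

struct Solver {
  int n;
  std::vector<std::vector<std::uint8_t>> adj; // n x n, symmetric, 0 diagonal
  std::vector<int> best;                      // incumbent clique (internal ids)
  std::vector<int> cur;

  bool connected(int u, int v) const { return adj[u][v] != 0; }

  // Greedy sequential colouring of the candidate list in its current order.
  // Rewrites cand sorted by colour class (ascending) and fills col with the
  // colour number of each rewritten position; col is an upper bound on the
  // clique size attainable from that prefix.
  void colour_sort(std::vector<int>& cand, std::vector<int>& col) {
    std::vector<std::vector<int>> classes;
    for (int v : cand) {
      std::size_t k = 0;
      for (; k < classes.size(); ++k) {
        bool clash = false;
        for (int u : classes[k]) {
          if (connected(u, v)) { clash = true; break; }
        }
        if (!clash) break;
      }
      if (k == classes.size()) classes.emplace_back();
      classes[k].push_back(v);
    }
    cand.clear();
    col.clear();
    for (std::size_t k = 0; k < classes.size(); ++k) {
      for (int v : classes[k]) {
        cand.push_back(v);
        col.push_back(static_cast<int>(k) + 1);
      }
    }
  }

  void expand(std::vector<int>& cand) {
    std::vector<int> col;
    colour_sort(cand, col);
    while (!cand.empty()) {
      int i = static_cast<int>(cand.size()) - 1;
      if (static_cast<int>(cur.size()) + col[i] <=
          static_cast<int>(best.size()))
        return; // colour bound prunes every remaining branch
      int v = cand[i];
      cand.pop_back();
      col.pop_back();
      cur.push_back(v);
      std::vector<int> next;
      next.reserve(cand.size());
      for (int u : cand)
        if (connected(u, v)) next.push_back(u);
      if (next.empty()) {
        if (cur.size() > best.size()) best = cur;
      } else {
        expand(next);
      }
      cur.pop_back();
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".max_clique_cpp")]]
Rcpp::IntegerVector max_clique_cpp(Rcpp::LogicalMatrix adjacency) {
  const int n = adjacency.nrow();
  if (adjacency.ncol() != n)
    Rcpp::stop("adjacency must be square");
  if (n == 0)
    return Rcpp::IntegerVector(0);

  Solver s;
  s.n = n;
  s.adj.assign(n, std::vector<std::uint8_t>(n, 0));
  std::vector<int> degree(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i != j && adjacency(i, j)) {
        s.adj[i][j] = 1;
        ++degree[i];
      }
    }
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (degree[a] != degree[b]) return degree[a] > degree[b];
    return a < b;
  });

  s.expand(order);

  Rcpp::IntegerVector out(s.best.size());
  for (std::size_t k = 0; k < s.best.size(); ++k)
    out[k] = s.best[k] + 1; // back to 1-based R indices
  std::sort(out.begin(), out.end());
  return out;
}
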