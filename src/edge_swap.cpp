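#include <Rcpp.h>
#include <unordered_set>

using namespace Rcpp;

// Degree-preserving randomization by repeated edge exchange: pick two edges
// a-b and c-d and replace them with a-d and c-b, provided neither new edge
// already exists and no self-loop arises. For bipartite networks the stored
// orientation (from-side / to-side) is fixed, which preserves layer
// membership; for undirected within-layer networks each picked edge's
// orientation is flipped with probability 1/2 so both pairings are
// reachable, and edge keys are canonicalized. Each edge's weight stays with
// its slot (i.e. travels with the first endpoint). Uses R's RNG, so results
// are reproducible under set.seed().

static inline uint64_t key_of(int a, int b, bool undirected) {
  int lo = a, hi = b;
  if (undirected && lo > hi) { lo = b; hi = a; }
  return (static_cast<uint64_t>(static_cast<uint32_t>(lo)) << 32) |
         static_cast<uint32_t>(hi);
}

// [[Rcpp::export]]
List edge_swap_cpp(IntegerVector from, IntegerVector to, int n_attempts,
                   bool undirected) {
  int m = from.size();
  std::vector<int> a(from.begin(), from.end());
  std::vector<int> b(to.begin(), to.end());
  std::unordered_set<uint64_t> edges;
  edges.reserve(m * 2);
  for (int i = 0; i < m; ++i) edges.insert(key_of(a[i], b[i], undirected));

  int n_success = 0;
  for (int t = 0; t < n_attempts; ++t) {
    int e1 = static_cast<int>(unif_rand() * m);
    int e2 = static_cast<int>(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
    if (undirected) {
      if (unif_rand() < 0.5) std::swap(x1, y1);
      if (unif_rand() < 0.5) std::swap(x2, y2);
    }
    // proposed: x1-y2 and x2-y1
    if (x1 == y2 || x2 == y1) continue;              // self-loop
    uint64_t k1 = key_of(x1, y2, undirected);
    uint64_t k2 = key_of(x2, y1, undirected);
    if (k1 == k2) continue;
    if (edges.count(k1) || edges.count(k2)) continue; // would duplicate
    edges.erase(key_of(a[e1], b[e1], undirected));
    edges.erase(key_of(a[e2], b[e2], undirected));
    edges.insert(k1);
    edges.insert(k2);
    a[e1] = x1; b[e1] = y2;
    a[e2] = x2; b[e2] = y1;
    ++n_success;
  }
  return List::create(_["from"] = wrap(a), _["to"] = wrap(b),
                      _["n_success"] = n_success);
}
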