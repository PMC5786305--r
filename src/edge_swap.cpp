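#include <Rcpp.h>
#include <unordered_set>
#include <random>
using namespace Rcpp;

// Degree-preserving double-edge swaps on a bipartite edge list.
// edges: E x 2 matrix of 1-based (disease index, gene index) pairs.
// A proposed swap (d1,g1),(d2,g2) -> (d1,g2),(d2,g1) is rejected when it
// would create a parallel edge; node colors and every node degree are
// preserved by construction. Deterministic per seed.
// [[Rcpp::export]]
List bipartite_swap_cpp(IntegerMatrix edges, int n_attempts, int seed) {
  const int E = edges.nrow();
  std::vector<int> d(E), g(E);
  std::unordered_set<uint64_t> present;
  present.reserve((size_t)E * 2);
  auto key = [](int a, int b) {
    return (uint64_t)(uint32_t)a << 32 | (uint32_t)b;
  };
  for (int e = 0; e < E; ++e) {
    d[e] = edges(e, 0);
    g[e] = edges(e, 1);
    present.insert(key(d[e], g[e]));
  }
  std::mt19937 gen((uint32_t)seed);
  int rejected = 0;
  for (int t = 0; t < n_attempts; ++t) {
    const int i = gen() % E;
    const int j = gen() % E;
    if (i == j) { ++rejected; continue; }
    if (d[i] == d[j] || g[i] == g[j]) { ++rejected; continue; }
    const uint64_t k1 = key(d[i], g[j]), k2 = key(d[j], g[i]);
    if (present.count(k1) || present.count(k2)) { ++rejected; continue; }
    present.erase(key(d[i], g[i]));
    present.erase(key(d[j], g[j]));
    std::swap(g[i], g[j]);
    present.insert(k1);
    present.insert(k2);
  }
  IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) { out(e, 0) = d[e]; out(e, 1) = g[e]; }
  return List::create(_["edges"] = out, _["rejected"] = rejected);
}
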