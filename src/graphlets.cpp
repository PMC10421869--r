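#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Orbit signatures for 2-4 node graphlets.
//
// Connected subgraphs are enumerated with the ESU scheme: each connected
// subgraph is visited exactly once from its minimal vertex under a given
// ordering.  For per-node counting we re-root the ordering so the query
// vertex is minimal, which turns ESU into an exact enumerator of the
// connected subsets containing that vertex.  Pairwise adjacency inside the
// current subset is tracked incrementally as bitmasks, so classifying a
// subgraph needs no further edge lookups.
//
// Orbit ids follow the standard convention for 2-4 node graphlets:
//   0  edge endpoint
//   1  path P3 end            2  path P3 middle
//   3  triangle
//   4  path P4 end            5  path P4 middle
//   6  claw K1,3 leaf         7  claw center
//   8  cycle C4
//   9  paw tail tip          10  paw cycle node (degree 2)
//  11  paw apex (degree 3)
//  12  diamond degree-2      13  diamond degree-3
//  14  K4

namespace {

struct Enumerator {
  int n;
  std::vector<std::vector<int>> adj; // sorted adjacency lists
  std::vector<char> seen;
  std::vector<int> ext;   // shared extension buffer across levels
  int sub[4];             // current subset, sub[0] is the root
  unsigned mask[4];       // mask[k]: adjacency of sub[k] to sub[0..k-1]
  int depth;              // number of nodes currently in sub
  int counts[15];

  bool has_edge(int a, int b) const {
    const std::vector<int>& v =
        adj[a].size() <= adj[b].size() ? adj[a] : adj[b];
    int other = adj[a].size() <= adj[b].size() ? b : a;
    return std::binary_search(v.begin(), v.end(), other);
  }

  // orbit of the root in the current (connected) subset
  int classify() const {
    if (depth == 2) return 0;

    int deg[4] = {0, 0, 0, 0};
    int nedges = 0;
    for (int k = 1; k < depth; ++k) {
      unsigned m = mask[k];
      while (m) {
        int j = __builtin_ctz(m);
        m &= m - 1;
        ++deg[k];
        ++deg[j];
        ++nedges;
      }
    }
    int rootdeg = deg[0];
    int maxdeg = *std::max_element(deg, deg + depth);

    if (depth == 3) {
      if (nedges == 3) return 3;
      return rootdeg == 1 ? 1 : 2; // P3
    }
    switch (nedges) {
    case 3:
      if (maxdeg == 3) return rootdeg == 1 ? 6 : 7; // claw
      return rootdeg == 1 ? 4 : 5;                  // P4
    case 4:
      if (maxdeg == 2) return 8; // C4
      if (rootdeg == 1) return 9;  // paw tail
      if (rootdeg == 2) return 10; // paw cycle
      return 11;                   // paw apex
    case 5:
      return rootdeg == 2 ? 12 : 13; // diamond
    default:
      return 14; // K4
    }
  }

  // extend over ext positions [lo, hi)
  void extend(int lo, int hi) {
    for (int i = lo; i < hi; ++i) {
      int w = ext[i];
      unsigned m = 0;
      for (int k = 0; k < depth; ++k) {
        if (has_edge(w, sub[k])) m |= 1u << k;
      }
      sub[depth] = w;
      mask[depth] = m;
      ++depth;
      counts[classify()]++;
      if (depth < 4) {
        int newhi = (int)ext.size();
        for (int u : adj[w]) {
          if (!seen[u]) {
            seen[u] = 1;
            ext.push_back(u);
          }
        }
        int grown = (int)ext.size();
        extend(i + 1, grown);
        for (int k = newhi; k < grown; ++k) seen[ext[k]] = 0;
        ext.resize(newhi);
      }
      --depth;
    }
  }

  void run_root(int root, int* out) {
    std::fill(counts, counts + 15, 0);
    seen[root] = 1;
    ext.clear();
    for (int u : adj[root]) {
      seen[u] = 1;
      ext.push_back(u);
    }
    sub[0] = root;
    mask[0] = 0;
    depth = 1;
    extend(0, (int)ext.size());
    seen[root] = 0;
    for (int u : adj[root]) seen[u] = 0;
    std::copy(counts, counts + 15, out);
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_count_orbits(int n_nodes, IntegerVector from, IntegerVector to,
                               IntegerVector targets) {
  Enumerator en;
  en.n = n_nodes;
  en.adj.assign(n_nodes, std::vector<int>());
  for (int e = 0; e < from.size(); ++e) {
    en.adj[from[e]].push_back(to[e]);
    en.adj[to[e]].push_back(from[e]);
  }
  for (int v = 0; v < n_nodes; ++v)
    std::sort(en.adj[v].begin(), en.adj[v].end());
  en.seen.assign(n_nodes, 0);
  en.ext.reserve(1024);

  IntegerMatrix out(targets.size(), 15);
  std::vector<int> row(15);
  for (int t = 0; t < targets.size(); ++t) {
    en.run_root(targets[t], row.data());
    for (int k = 0; k < 15; ++k) out(t, k) = row[k];
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
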