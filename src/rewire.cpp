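// Degree-preserving rewiring by double-edge swaps, restricted so that
// intra-brain-1, intra-brain-2 and inter-brain edges each rewire only within
// their own class (this preserves the intra- and inter-brain degree
// sequences of a hyperbrain network separately).  In lattice mode a swap is
// accepted only when it does not increase the total "lattice cost": ring
// distance between within-brain node positions for intra edges, absolute
// position offset for inter edges, so edges migrate toward a banded layout.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix rewire_blocks_cpp(IntegerMatrix adj, IntegerVector brain,
                                bool lattice, int attempts_per_edge) {
  const int n = adj.nrow();
  IntegerMatrix a = clone(adj);
  for (int i = 0; i < n; ++i) a(i, i) = 0;  // self-connections never rewired

  // within-brain position and brain sizes
  std::vector<int> pos(n), bsize(3, 0);
  for (int i = 0; i < n; ++i) {
    int b = brain[i];
    pos[i] = bsize[b];
    bsize[b]++;
  }
  auto cost = [&](int u, int v) {
    if (brain[u] == brain[v]) {
      int d = std::abs(pos[u] - pos[v]);
      int nb = bsize[brain[u]];
      return std::min(d, nb - d);
    }
    return std::abs(pos[u] - pos[v]);
  };

  // edge classes: 0 = intra first brain, 1 = intra second brain, 2 = inter
  std::vector<std::vector<std::pair<int, int>>> edges(3);
  int b1 = brain[0];
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j)) {
        if (brain[i] == brain[j])
          edges[brain[i] == b1 ? 0 : 1].push_back({i, j});
        else  // store as (first brain node, second brain node)
          edges[2].push_back(brain[i] == b1 ? std::make_pair(i, j)
                                            : std::make_pair(j, i));
      }

  for (int cls = 0; cls < 3; ++cls) {
    auto& E = edges[cls];
    const int m = (int)E.size();
    if (m < 2) continue;
    long attempts = (long)attempts_per_edge * m;
    for (long t = 0; t < attempts; ++t) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 == e2) continue;
      int u1 = E[e1].first, v1 = E[e1].second;
      int u2 = E[e2].first, v2 = E[e2].second;
      if (cls != 2 && unif_rand() < 0.5) std::swap(u2, v2);
      // proposed: (u1, v2) and (u2, v1)
      if (u1 == v2 || u2 == v1) continue;
      if (u1 == u2 || v1 == v2) continue;
      if (a(u1, v2) || a(u2, v1)) continue;
      if (lattice &&
          cost(u1, v2) + cost(u2, v1) > cost(u1, v1) + cost(u2, v2))
        continue;
      a(u1, v1) = a(v1, u1) = 0;
      a(u2, v2) = a(v2, u2) = 0;
      a(u1, v2) = a(v2, u1) = 1;
      a(u2, v1) = a(v1, u2) = 1;
      E[e1] = {u1, v2};
      E[e2] = {u2, v1};
      if (cls == 2) {  // keep (brain1, brain2) orientation
        if (brain[E[e1].first] != b1) std::swap(E[e1].first, E[e1].second);
        if (brain[E[e2].first] != b1) std::swap(E[e2].first, E[e2].second);
      } else {
        if (E[e1].first > E[e1].second) std::swap(E[e1].first, E[e1].second);
        if (E[e2].first > E[e2].second) std::swap(E[e2].first, E[e2].second);
      }
    }
  }
  return a;
}
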