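#include <Rcpp.h>
using namespace Rcpp;

// Balance-constrained single-node-move refinement of a k-way partition.
// CSR adjacency (0-based), integer edge weights (the cut objective), and
// integer node weights (gene counts, so coarse-level supernodes count for
// the genes they contain).  A node moves to the part maximising its
// connection weight when the gain is strictly positive, the target part
// stays within `cap` and its own part keeps positive weight.  Sweeps nodes
// in the supplied order until a full sweep makes no move (a local optimum
// under single-node moves) or `max_passes` is hit.
// [[Rcpp::export]]
IntegerVector refine_partition_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                                   IntegerVector adj_w, IntegerVector vwgt,
                                   IntegerVector assign, int k, int cap,
                                   int max_passes, IntegerVector order) {
  int n = assign.size();
  IntegerVector part = clone(assign);           // 0-based part labels
  std::vector<long long> size(k, 0);
  for (int i = 0; i < n; ++i) size[part[i]] += vwgt[i];
  std::vector<long long> conn(k, 0);
  std::vector<int> touched;
  touched.reserve(64);

  for (int pass = 0; pass < max_passes; ++pass) {
    bool moved = false;
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      int pv = part[v];
      if (size[pv] <= vwgt[v]) continue;        // would empty the part
      touched.clear();
      for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
        int u = adj_idx[e];
        int pu = part[u];
        if (conn[pu] == 0) touched.push_back(pu);
        conn[pu] += adj_w[e];
      }
      long long own = 0, best = 0;
      int best_p = -1;
      for (size_t t = 0; t < touched.size(); ++t) {
        int p = touched[t];
        if (p == pv) { own = conn[p]; continue; }
        if (size[p] + vwgt[v] > cap) continue;
        if (conn[p] > best || (conn[p] == best && best_p >= 0 && p < best_p)) {
          best = conn[p];
          best_p = p;
        }
      }
      if (best_p >= 0 && best > own) {
        size[pv] -= vwgt[v]; size[best_p] += vwgt[v];
        part[v] = best_p;
        moved = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) conn[touched[t]] = 0;
    }
    if (!moved) break;
  }
  return part;
}

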