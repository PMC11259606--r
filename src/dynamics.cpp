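#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving; tie-break data: component size and smallest
// contained node index.
struct UF {
  std::vector<int> parent, size, minnode;
  void init(int n) {
    parent.resize(n); size.assign(n, 1); minnode.resize(n);
    for (int i = 0; i < n; ++i) { parent[i] = i; minnode[i] = i; }
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    if (minnode[b] < minnode[a]) minnode[a] = minnode[b];
  }
};

// Step 1: nodes active iff in the largest connected component of the
// active-link subgraph. A largest component of size < 2 (no active link)
// deactivates everything; exact size ties go to the component containing the
// smallest node index.
static void step1(int N, const IntegerMatrix& edges,
                  const std::vector<char>& link_active, UF& uf,
                  std::vector<char>& node_active) {
  uf.init(N);
  int E = edges.nrow();
  for (int l = 0; l < E; ++l) {
    if (link_active[l]) uf.unite(edges(l, 0) - 1, edges(l, 1) - 1);
  }
  int best = -1, best_size = 1, best_min = N;  // require size >= 2
  for (int i = 0; i < N; ++i) {
    if (uf.find(i) != i) continue;
    if (uf.size[i] > best_size ||
        (uf.size[i] == best_size && uf.minnode[i] < best_min)) {
      best = i; best_size = uf.size[i]; best_min = uf.minnode[i];
    }
  }
  if (best < 0 || best_size < 2) {
    std::fill(node_active.begin(), node_active.end(), 0);
    return;
  }
  for (int i = 0; i < N; ++i) node_active[i] = (uf.find(i) == best);
}

// Step 2: a link stays active iff it has no active negative regulator, at
// least one active positive regulator, and (for p < 1) an independent
// Bernoulli(p) success. Regulators in CSR layout (0-based node ids).
static void step2(int E, const std::vector<char>& node_active,
                  const IntegerVector& pos_ptr, const IntegerVector& pos_idx,
                  const IntegerVector& neg_ptr, const IntegerVector& neg_idx,
                  double p, std::vector<char>& link_active) {
  for (int l = 0; l < E; ++l) {
    link_active[l] = 0;
    bool veto = false;
    for (int k = neg_ptr[l]; k < neg_ptr[l + 1]; ++k) {
      if (node_active[neg_idx[k]]) { veto = true; break; }
    }
    if (veto) continue;
    bool boost = false;
    for (int k = pos_ptr[l]; k < pos_ptr[l + 1]; ++k) {
      if (node_active[pos_idx[k]]) { boost = true; break; }
    }
    if (!boost) continue;
    if (p < 1.0 && unif_rand() >= p) continue;
    link_active[l] = 1;
  }
}

// [[Rcpp::export]]
LogicalVector largest_component_cpp(int N, IntegerMatrix edges,
                                    LogicalVector link_active) {
  std::vector<char> la(edges.nrow());
  for (int l = 0; l < edges.nrow(); ++l) la[l] = link_active[l];
  std::vector<char> na(N);
  UF uf;
  step1(N, edges, la, uf, na);
  LogicalVector out(N);
  for (int i = 0; i < N; ++i) out[i] = (bool)na[i];
  return out;
}

// [[Rcpp::export]]
LogicalVector update_links_cpp(int N, int E, LogicalVector node_active,
                               IntegerVector pos_ptr, IntegerVector pos_idx,
                               IntegerVector neg_ptr, IntegerVector neg_idx,
                               double p) {
  std::vector<char> na(N), la(E);
  for (int i = 0; i < N; ++i) na[i] = node_active[i];
  step2(E, na, pos_ptr, pos_idx, neg_ptr, neg_idx, p, la);
  LogicalVector out(E);
  for (int l = 0; l < E; ++l) out[l] = (bool)la[l];
  return out;
}

// Full trajectory. State 0 applies Step 1 to the all-links-active initial
// condition, then Step 2; each later state is one full two-step iteration.
// Returns node states as a (steps + 1) x N logical matrix, the giant-component
// fraction series, and the final link configuration.
// [[Rcpp::export]]
List run_dynamics_cpp(int N, IntegerMatrix edges,
                      IntegerVector pos_ptr, IntegerVector pos_idx,
                      IntegerVector neg_ptr, IntegerVector neg_idx,
                      double p, int steps) {
  int E = edges.nrow();
  std::vector<char> link_active(E, 1), node_active(N, 0);
  LogicalMatrix node_states(steps + 1, N);
  NumericVector R(steps + 1);
  UF uf;
  for (int t = 0; t <= steps; ++t) {
    step1(N, edges, link_active, uf, node_active);
    int act = 0;
    for (int i = 0; i < N; ++i) {
      node_states(t, i) = (bool)node_active[i];
      act += node_active[i];
    }
    R[t] = (double)act / N;
    step2(E, node_active, pos_ptr, pos_idx, neg_ptr, neg_idx, p, link_active);
  }
  LogicalVector lf(E);
  for (int l = 0; l < E; ++l) lf[l] = (bool)link_active[l];
  return List::create(_["node_states"] = node_states, _["R"] = R,
                      _["link_final"] = lf);
}
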