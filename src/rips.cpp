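#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>
using namespace Rcpp;

// Vietoris-Rips persistence in dimensions 0 and 1 from a distance matrix,
// with simplices up to dimension 2 and filtration capped at `cap`
// (simplex included iff its diameter <= cap).
//
// H0: union-find over the edge filtration; every merge kills one class
// (birth 0); each connected component at the cap contributes one essential
// class with death = cap.
//
// H1: GF(2) column reduction of the triangle boundary matrix in filtration
// order. Only triangle columns can be added to triangle columns, so reducing
// the dimension-2 block alone reproduces the dimension-1 pairs of the full
// reduction; the pivot (lowest nonzero row) of a reduced triangle column is
// the cycle-creating edge it kills. Cycle edges never claimed as pivots are
// essential classes with death = cap.

struct EdgeRec { double d; int i, j; };
struct TriRec { double d; int e1, e2, e3; };  // edge ranks, ascending

static void symdiff(std::vector<int>& a, const std::vector<int>& b,
                    std::vector<int>& tmp) {
  tmp.clear();
  size_t x = 0, y = 0;
  while (x < a.size() && y < b.size()) {
    if (a[x] < b[y]) tmp.push_back(a[x++]);
    else if (b[y] < a[x]) tmp.push_back(b[y++]);
    else { ++x; ++y; }
  }
  while (x < a.size()) tmp.push_back(a[x++]);
  while (y < b.size()) tmp.push_back(b[y++]);
  a.swap(tmp);
}

// [[Rcpp::export]]
List rips_pairs_cpp(NumericMatrix D, double cap) {
  int n = D.nrow();
  std::vector<double> h0b, h0d, h1b, h1d;
  if (n == 0) {
    return List::create(
      _["H0"] = NumericMatrix(0, 2), _["H1"] = NumericMatrix(0, 2));
  }

  // --- edges under the cap, filtration order ---
  std::vector<EdgeRec> edges;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = D(i, j);
      if (d <= cap) edges.push_back({d, i, j});
    }
  }
  std::sort(edges.begin(), edges.end(), [](const EdgeRec& a, const EdgeRec& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  int E = (int)edges.size();

  // edge rank lookup (i * n + j, i < j)
  std::vector<int> rank_of((size_t)n * n, -1);
  for (int e = 0; e < E; ++e) {
    rank_of[(size_t)edges[e].i * n + edges[e].j] = e;
  }

  // --- H0 via union-find; mark cycle (positive) edges ---
  std::vector<int> parent(n), sz(n, 1);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<char> positive(E, 0);
  for (int e = 0; e < E; ++e) {
    int a = find(edges[e].i), b = find(edges[e].j);
    if (a == b) { positive[e] = 1; continue; }
    if (sz[a] < sz[b]) std::swap(a, b);
    parent[b] = a; sz[a] += sz[b];
    if (edges[e].d > 0) { h0b.push_back(0.0); h0d.push_back(edges[e].d); }
  }
  int comps = 0;
  for (int i = 0; i < n; ++i) if (find(i) == i) ++comps;
  for (int k = 0; k < comps; ++k) { h0b.push_back(0.0); h0d.push_back(cap); }

  // --- triangles under the cap ---
  std::vector<TriRec> tris;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dij = D(i, j);
      if (dij > cap) continue;
      for (int k = j + 1; k < n; ++k) {
        double dik = D(i, k), djk = D(j, k);
        if (dik > cap || djk > cap) continue;
        double diam = std::max(dij, std::max(dik, djk));
        int e1 = rank_of[(size_t)i * n + j];
        int e2 = rank_of[(size_t)i * n + k];
        int e3 = rank_of[(size_t)j * n + k];
        int lo = std::min(e1, std::min(e2, e3));
        int hi = std::max(e1, std::max(e2, e3));
        int mid = e1 + e2 + e3 - lo - hi;
        tris.push_back({diam, lo, mid, hi});
      }
    }
  }
  // filtration order; ties broken by the (already filtration-ordered) edge
  // ranks so the order is deterministic
  std::sort(tris.begin(), tris.end(), [](const TriRec& a, const TriRec& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.e3 != b.e3) return a.e3 < b.e3;
    if (a.e2 != b.e2) return a.e2 < b.e2;
    return a.e1 < b.e1;
  });

  // --- boundary reduction over GF(2) ---
  std::vector<int> pivot(E, -1);          // edge rank -> stored column id
  std::vector<std::vector<int> > stored;  // reduced columns, sorted ascending
  std::vector<double> death_of(E, -1.0);
  std::vector<int> col, tmp;
  for (size_t t = 0; t < tris.size(); ++t) {
    col.clear();
    col.push_back(tris[t].e1); col.push_back(tris[t].e2); col.push_back(tris[t].e3);
    while (!col.empty()) {
      int low = col.back();
      int pi = pivot[low];
      if (pi < 0) {
        pivot[low] = (int)stored.size();
        stored.push_back(col);
        death_of[low] = tris[t].d;
        break;
      }
      symdiff(col, stored[pi], tmp);
    }
  }

  for (int e = 0; e < E; ++e) {
    if (!positive[e]) continue;
    double birth = edges[e].d;
    double death = (pivot[e] >= 0) ? death_of[e] : cap;
    if (death > birth) { h1b.push_back(birth); h1d.push_back(death); }
  }

  NumericMatrix H0(h0b.size(), 2), H1(h1b.size(), 2);
  for (size_t k = 0; k < h0b.size(); ++k) { H0(k, 0) = h0b[k]; H0(k, 1) = h0d[k]; }
  for (size_t k = 0; k < h1b.size(); ++k) { H1(k, 0) = h1b[k]; H1(k, 1) = h1d[k]; }
  return List::create(_["H0"] = H0, _["H1"] = H1);
}
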