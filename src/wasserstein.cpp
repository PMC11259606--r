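#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Order-1 Wasserstein matching distance between persistence diagrams with the
// L-infinity ground metric; unmatched points pay their L-infinity distance to
// the diagonal, (death - birth) / 2.

// Fast path for diagrams whose births are all zero (Rips H0): the problem is
// one-dimensional transport on the death values with deletion penalty d / 2,
// and an optimal matching can be taken monotone, so a O(nm) dynamic program
// over the sorted death vectors is exact.
// [[Rcpp::export]]
double w1_zero_birth_cpp(NumericVector deaths1, NumericVector deaths2) {
  std::vector<double> a(deaths1.begin(), deaths1.end());
  std::vector<double> b(deaths2.begin(), deaths2.end());
  std::sort(a.begin(), a.end());
  std::sort(b.begin(), b.end());
  size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  prev[0] = 0.0;
  for (size_t j = 1; j <= m; ++j) prev[j] = prev[j - 1] + b[j - 1] / 2.0;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = prev[0] + a[i - 1] / 2.0;
    for (size_t j = 1; j <= m; ++j) {
      double best = prev[j - 1] + std::fabs(a[i - 1] - b[j - 1]);
      double del_a = prev[j] + a[i - 1] / 2.0;
      double del_b = cur[j - 1] + b[j - 1] / 2.0;
      if (del_a < best) best = del_a;
      if (del_b < best) best = del_b;
      cur[j] = best;
    }
    prev.swap(cur);
  }
  return prev[m];
}

// Exact assignment (Hungarian algorithm with potentials) on the standard
// augmented matrix: each diagram point may match a point of the other diagram
// or its own diagonal projection; diagonal-to-diagonal pairs cost zero.
// [[Rcpp::export]]
double w1_diagrams_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  if (na == 0 && nb == 0) return 0.0;
  const double INF = 1e18, BIG = 1e9;
  int n = na + nb;
  std::vector<std::vector<double> > a(n + 1, std::vector<double>(n + 1, 0.0));
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= n; ++j) {
      double cost;
      if (i <= na && j <= nb) {
        cost = std::max(std::fabs(A(i - 1, 0) - B(j - 1, 0)),
                        std::fabs(A(i - 1, 1) - B(j - 1, 1)));
      } else if (i <= na) {          // A point vs diagonal slot
        cost = (j - nb == i) ? (A(i - 1, 1) - A(i - 1, 0)) / 2.0 : BIG;
      } else if (j <= nb) {          // diagonal slot vs B point
        cost = (i - na == j) ? (B(j - 1, 1) - B(j - 1, 0)) / 2.0 : BIG;
      } else {
        cost = 0.0;                  // diagonal-diagonal
      }
      a[i][j] = cost;
    }
  }
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  std::vector<char> used(n + 1);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(used.begin(), used.end(), 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a[i0][j] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double total = 0.0;
  for (int j = 1; j <= n; ++j) total += a[p[j]][j];
  return total;
}
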