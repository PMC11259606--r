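#include <Rcpp.h>
using namespace Rcpp;

static inline double torus_d(double ax, double ay, double bx, double by,
                             double Lx, double Ly) {
  double dx = std::fabs(ax - bx);
  if (dx > Lx - dx) dx = Lx - dx;
  double dy = std::fabs(ay - by);
  if (dy > Ly - dy) dy = Ly - dy;
  return std::sqrt(dx * dx + dy * dy);
}

// [[Rcpp::export]]
NumericMatrix torus_dist_matrix_cpp(NumericMatrix pts, double Lx, double Ly) {
  int n = pts.nrow();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = torus_d(pts(i, 0), pts(i, 1), pts(j, 0), pts(j, 1), Lx, Ly);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Waxman sampler: each unordered pair (i, j) independently with probability
// c * exp(-d_ij / d0). Uses the R RNG; returns 1-based edge indices.
// [[Rcpp::export]]
IntegerMatrix sample_structural_cpp(NumericMatrix pts, double c, double d0,
                                    double Lx, double Ly) {
  int n = pts.nrow();
  std::vector<int> us, vs;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = torus_d(pts(i, 0), pts(i, 1), pts(j, 0), pts(j, 1), Lx, Ly);
      double p = c * std::exp(-d / d0);
      if (unif_rand() < p) {
        us.push_back(i + 1);
        vs.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(us.size(), 2);
  for (size_t k = 0; k < us.size(); ++k) {
    out(k, 0) = us[k];
    out(k, 1) = vs[k];
  }
  return out;
}

// Signed regulatory sampler: one categorical draw per (node, link midpoint)
// pair, positive with probability c+ exp(-d/dr+), negative with probability
// c- exp(-d/dr-), nothing otherwise. Mutually exclusive by construction.
// Pairs with total probability below 1e-14 skip the RNG draw.
// Returns columns (regulator, edge, sign), 1-based.
// [[Rcpp::export]]
IntegerMatrix sample_regulatory_cpp(NumericMatrix pts, NumericMatrix mids,
                                    double cplus, double cminus,
                                    double drplus, double drminus,
                                    double Lx, double Ly) {
  int n = pts.nrow(), m = mids.nrow();
  std::vector<int> reg, edge, sgn;
  for (int l = 0; l < m; ++l) {
    double mx = mids(l, 0), my = mids(l, 1);
    for (int i = 0; i < n; ++i) {
      double d = torus_d(pts(i, 0), pts(i, 1), mx, my, Lx, Ly);
      double pp = cplus * std::exp(-d / drplus);
      double pm = cminus * std::exp(-d / drminus);
      if (pp + pm < 1e-14) continue;
      double u = unif_rand();
      if (u < pp) {
        reg.push_back(i + 1); edge.push_back(l + 1); sgn.push_back(1);
      } else if (u < pp + pm) {
        reg.push_back(i + 1); edge.push_back(l + 1); sgn.push_back(-1);
      }
    }
  }
  IntegerMatrix out(reg.size(), 3);
  for (size_t k = 0; k < reg.size(); ++k) {
    out(k, 0) = reg[k];
    out(k, 1) = edge[k];
    out(k, 2) = sgn[k];
  }
  return out;
}
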