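#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Raster-scan geodesic distance transform.
// Edge cost between adjacent grid points is the Euclidean norm of the
// channel-wise intensity difference (pure gradient cost: no additive spatial
// term and no sqrt(2) scaling on diagonal steps, so distances on a constant
// image are identically zero and anisotropic spacing plays no role).
// Forward and backward scans form one pass pair; pairs repeat until the
// largest update falls below `tol` or `max_pairs` pairs have run.

static inline double edge2d(const double *X, R_xlen_t plane, int n1, int i,
                            int j, int ci) {
  double s = 0.0;
  for (int c = 0; c < ci; ++c) {
    const double d = X[i + c * plane] - X[j + c * plane];
    s += d * d;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
List cpp_geodesic2d(NumericVector x, IntegerMatrix seeds, double tol,
                    int max_pairs) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], ci = xd[2];
  const R_xlen_t plane = static_cast<R_xlen_t>(n1) * n2;
  const double INF = R_PosInf;
  NumericVector dist(plane, INF);
  dist.attr("dim") = IntegerVector::create(n1, n2);
  for (int s = 0; s < seeds.nrow(); ++s)
    dist[seeds(s, 0) + static_cast<R_xlen_t>(seeds(s, 1)) * n1] = 0.0;
  const double *X = x.begin();
  double *D = dist.begin();
  // forward-pass neighbour offsets (already-visited half of the 3x3 kernel)
  const int off1[4] = {-1, 0, 1, -1};
  const int off2[4] = {-1, -1, -1, 0};
  int pairs = 0;
  bool converged = false;
  while (pairs < max_pairs && !converged) {
    double maxchg = 0.0;
    // forward scan
    for (int p2 = 0; p2 < n2; ++p2)
      for (int p1 = 0; p1 < n1; ++p1) {
        const R_xlen_t pi = p1 + static_cast<R_xlen_t>(p2) * n1;
        double best = D[pi];
        for (int o = 0; o < 4; ++o) {
          const int s1 = p1 + off1[o], s2 = p2 + off2[o];
          if (s1 < 0 || s1 >= n1 || s2 < 0 || s2 >= n2) continue;
          const R_xlen_t si = s1 + static_cast<R_xlen_t>(s2) * n1;
          if (D[si] == INF) continue;
          const double cand = D[si] + edge2d(X, plane, n1, (int)pi, (int)si, ci);
          if (cand < best) best = cand;
        }
        if (best < D[pi]) {
          const double chg = (D[pi] == INF) ? INF : D[pi] - best;
          if (chg > maxchg) maxchg = chg;
          D[pi] = best;
        }
      }
    // backward scan
    for (int p2 = n2 - 1; p2 >= 0; --p2)
      for (int p1 = n1 - 1; p1 >= 0; --p1) {
        const R_xlen_t pi = p1 + static_cast<R_xlen_t>(p2) * n1;
        double best = D[pi];
        for (int o = 0; o < 4; ++o) {
          const int s1 = p1 - off1[o], s2 = p2 - off2[o];
          if (s1 < 0 || s1 >= n1 || s2 < 0 || s2 >= n2) continue;
          const R_xlen_t si = s1 + static_cast<R_xlen_t>(s2) * n1;
          if (D[si] == INF) continue;
          const double cand = D[si] + edge2d(X, plane, n1, (int)pi, (int)si, ci);
          if (cand < best) best = cand;
        }
        if (best < D[pi]) {
          const double chg = (D[pi] == INF) ? INF : D[pi] - best;
          if (chg > maxchg) maxchg = chg;
          D[pi] = best;
        }
      }
    ++pairs;
    converged = (maxchg <= tol);
  }
  return List::create(_["dist"] = dist, _["pairs"] = pairs,
                      _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_geodesic3d(NumericVector x, IntegerMatrix seeds, double tol,
                    int max_pairs) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], ci = xd[3];
  const R_xlen_t vol = static_cast<R_xlen_t>(n1) * n2 * n3;
  const double INF = R_PosInf;
  NumericVector dist(vol, INF);
  dist.attr("dim") = IntegerVector::create(n1, n2, n3);
  for (int s = 0; s < seeds.nrow(); ++s)
    dist[seeds(s, 0) +
         n1 * (seeds(s, 1) + static_cast<R_xlen_t>(n2) * seeds(s, 2))] = 0.0;
  const double *X = x.begin();
  double *D = dist.begin();
  // 13 already-visited neighbours of the 3x3x3 kernel in scan order
  int off[13][3];
  {
    int m = 0;
    for (int a3 = -1; a3 <= 1; ++a3)
      for (int a2 = -1; a2 <= 1; ++a2)
        for (int a1 = -1; a1 <= 1; ++a1) {
          if (a3 < 0 || (a3 == 0 && (a2 < 0 || (a2 == 0 && a1 < 0)))) {
            off[m][0] = a1;
            off[m][1] = a2;
            off[m][2] = a3;
            ++m;
          }
        }
  }
  int pairs = 0;
  bool converged = false;
  while (pairs < max_pairs && !converged) {
    double maxchg = 0.0;
    for (int dir = 0; dir < 2; ++dir) {
      const int sgn = dir == 0 ? 1 : -1;
      for (int t3 = 0; t3 < n3; ++t3)
        for (int t2 = 0; t2 < n2; ++t2)
          for (int t1 = 0; t1 < n1; ++t1) {
            const int p1 = dir == 0 ? t1 : n1 - 1 - t1;
            const int p2 = dir == 0 ? t2 : n2 - 1 - t2;
            const int p3 = dir == 0 ? t3 : n3 - 1 - t3;
            const R_xlen_t pi =
                p1 + n1 * (p2 + static_cast<R_xlen_t>(n2) * p3);
            double best = D[pi];
            for (int o = 0; o < 13; ++o) {
              const int s1 = p1 + sgn * off[o][0];
              const int s2 = p2 + sgn * off[o][1];
              const int s3 = p3 + sgn * off[o][2];
              if (s1 < 0 || s1 >= n1 || s2 < 0 || s2 >= n2 || s3 < 0 ||
                  s3 >= n3)
                continue;
              const R_xlen_t si =
                  s1 + n1 * (s2 + static_cast<R_xlen_t>(n2) * s3);
              if (D[si] == INF) continue;
              double w = 0.0;
              for (int c = 0; c < ci; ++c) {
                const double dd = X[pi + c * vol] - X[si + c * vol];
                w += dd * dd;
              }
              const double cand = D[si] + std::sqrt(w);
              if (cand < best) best = cand;
            }
            if (best < D[pi]) {
              const double chg = (D[pi] == INF) ? INF : D[pi] - best;
              if (chg > maxchg) maxchg = chg;
              D[pi] = best;
            }
          }
    }
    ++pairs;
    converged = (maxchg <= tol);
  }
  return List::create(_["dist"] = dist, _["pairs"] = pairs,
                      _["converged"] = converged);
}
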