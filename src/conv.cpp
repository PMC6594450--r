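#include <Rcpp.h>
using namespace Rcpp;

// Dilated convolution, column-major arrays.
// x: (n1, n2, ci), w: (k, k, ci, co), y(p) = b[oc] +
//   sum_{a1,a2 in [-r,r]} x(p1 - q*a1, p2 - q*a2, ic) * w(a1+r, a2+r, ic, oc)
// Zero padding outside the grid, so the output extent equals the input extent.

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector bias,
                         int q) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int n1 = xd[0], n2 = xd[1], ci = xd[2];
  const int k = wd[0], co = wd[3];
  const int r = (k - 1) / 2;
  NumericVector y(static_cast<R_xlen_t>(n1) * n2 * co);
  y.attr("dim") = IntegerVector::create(n1, n2, co);
  const double *X = x.begin(), *W = w.begin();
  double *Y = y.begin();
  for (int oc = 0; oc < co; ++oc) {
    for (int p2 = 0; p2 < n2; ++p2) {
      for (int p1 = 0; p1 < n1; ++p1) {
        double acc = bias[oc];
        for (int ic = 0; ic < ci; ++ic) {
          const double *Xc = X + static_cast<R_xlen_t>(ic) * n1 * n2;
          const double *Wc = W + (static_cast<R_xlen_t>(oc) * ci + ic) * k * k;
          for (int a2 = -r; a2 <= r; ++a2) {
            const int s2 = p2 - q * a2;
            if (s2 < 0 || s2 >= n2) continue;
            for (int a1 = -r; a1 <= r; ++a1) {
              const int s1 = p1 - q * a1;
              if (s1 < 0 || s1 >= n1) continue;
              acc += Xc[s1 + static_cast<R_xlen_t>(s2) * n1] *
                     Wc[(a1 + r) + (a2 + r) * k];
            }
          }
        }
        Y[p1 + static_cast<R_xlen_t>(p2) * n1 +
          static_cast<R_xlen_t>(oc) * n1 * n2] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_grad(NumericVector x, NumericVector w, NumericVector gy,
                     int q) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int n1 = xd[0], n2 = xd[1], ci = xd[2];
  const int k = wd[0], co = wd[3];
  const int r = (k - 1) / 2;
  NumericVector gx(static_cast<R_xlen_t>(n1) * n2 * ci);
  gx.attr("dim") = IntegerVector::create(n1, n2, ci);
  NumericVector gw(static_cast<R_xlen_t>(k) * k * ci * co);
  gw.attr("dim") = IntegerVector::create(k, k, ci, co);
  NumericVector gb(co);
  const double *X = x.begin(), *W = w.begin(), *GY = gy.begin();
  double *GX = gx.begin(), *GW = gw.begin();
  for (int oc = 0; oc < co; ++oc) {
    const double *Gc = GY + static_cast<R_xlen_t>(oc) * n1 * n2;
    double acc_b = 0.0;
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(n1) * n2; ++i)
      acc_b += Gc[i];
    gb[oc] = acc_b;
    for (int ic = 0; ic < ci; ++ic) {
      const double *Xc = X + static_cast<R_xlen_t>(ic) * n1 * n2;
      const double *Wc = W + (static_cast<R_xlen_t>(oc) * ci + ic) * k * k;
      double *GXc = GX + static_cast<R_xlen_t>(ic) * n1 * n2;
      double *GWc = GW + (static_cast<R_xlen_t>(oc) * ci + ic) * k * k;
      for (int a2 = -r; a2 <= r; ++a2) {
        for (int a1 = -r; a1 <= r; ++a1) {
          const double wv = Wc[(a1 + r) + (a2 + r) * k];
          double acc_w = 0.0;
          for (int p2 = 0; p2 < n2; ++p2) {
            const int s2 = p2 - q * a2;
            if (s2 < 0 || s2 >= n2) continue;
            for (int p1 = 0; p1 < n1; ++p1) {
              const int s1 = p1 - q * a1;
              if (s1 < 0 || s1 >= n1) continue;
              const double g = Gc[p1 + static_cast<R_xlen_t>(p2) * n1];
              const R_xlen_t si = s1 + static_cast<R_xlen_t>(s2) * n1;
              acc_w += g * Xc[si];
              GXc[si] += g * wv;
            }
          }
          GWc[(a1 + r) + (a2 + r) * k] += acc_w;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// x: (n1, n2, n3, ci), w: (k, k, k, ci, co)

// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, NumericVector w, NumericVector bias,
                         int q) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], ci = xd[3];
  const int k = wd[0], co = wd[4];
  const int r = (k - 1) / 2;
  const R_xlen_t vol = static_cast<R_xlen_t>(n1) * n2 * n3;
  NumericVector y(vol * co);
  y.attr("dim") = IntegerVector::create(n1, n2, n3, co);
  const double *X = x.begin(), *W = w.begin();
  double *Y = y.begin();
  for (int oc = 0; oc < co; ++oc) {
    for (int p3 = 0; p3 < n3; ++p3)
      for (int p2 = 0; p2 < n2; ++p2)
        for (int p1 = 0; p1 < n1; ++p1) {
          double acc = bias[oc];
          for (int ic = 0; ic < ci; ++ic) {
            const double *Xc = X + static_cast<R_xlen_t>(ic) * vol;
            const double *Wc =
                W + (static_cast<R_xlen_t>(oc) * ci + ic) * k * k * k;
            for (int a3 = -r; a3 <= r; ++a3) {
              const int s3 = p3 - q * a3;
              if (s3 < 0 || s3 >= n3) continue;
              for (int a2 = -r; a2 <= r; ++a2) {
                const int s2 = p2 - q * a2;
                if (s2 < 0 || s2 >= n2) continue;
                for (int a1 = -r; a1 <= r; ++a1) {
                  const int s1 = p1 - q * a1;
                  if (s1 < 0 || s1 >= n1) continue;
                  acc += Xc[s1 + n1 * (s2 + static_cast<R_xlen_t>(n2) * s3)] *
                         Wc[(a1 + r) + k * ((a2 + r) + k * (a3 + r))];
                }
              }
            }
          }
          Y[p1 + n1 * (p2 + static_cast<R_xlen_t>(n2) * p3) + oc * vol] = acc;
        }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_grad(NumericVector x, NumericVector w, NumericVector gy,
                     int q) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], ci = xd[3];
  const int k = wd[0], co = wd[4];
  const int r = (k - 1) / 2;
  const R_xlen_t vol = static_cast<R_xlen_t>(n1) * n2 * n3;
  NumericVector gx(vol * ci);
  gx.attr("dim") = IntegerVector::create(n1, n2, n3, ci);
  NumericVector gw(static_cast<R_xlen_t>(k) * k * k * ci * co);
  gw.attr("dim") = IntegerVector::create(k, k, k, ci, co);
  NumericVector gb(co);
  const double *X = x.begin(), *W = w.begin(), *GY = gy.begin();
  double *GX = gx.begin(), *GW = gw.begin();
  for (int oc = 0; oc < co; ++oc) {
    const double *Gc = GY + oc * vol;
    double acc_b = 0.0;
    for (R_xlen_t i = 0; i < vol; ++i) acc_b += Gc[i];
    gb[oc] = acc_b;
    for (int ic = 0; ic < ci; ++ic) {
      const double *Xc = X + static_cast<R_xlen_t>(ic) * vol;
      const double *Wc = W + (static_cast<R_xlen_t>(oc) * ci + ic) * k * k * k;
      double *GXc = GX + static_cast<R_xlen_t>(ic) * vol;
      double *GWc = GW + (static_cast<R_xlen_t>(oc) * ci + ic) * k * k * k;
      for (int a3 = -r; a3 <= r; ++a3)
        for (int a2 = -r; a2 <= r; ++a2)
          for (int a1 = -r; a1 <= r; ++a1) {
            const int wi = (a1 + r) + k * ((a2 + r) + k * (a3 + r));
            const double wv = Wc[wi];
            double acc_w = 0.0;
            for (int p3 = 0; p3 < n3; ++p3) {
              const int s3 = p3 - q * a3;
              if (s3 < 0 || s3 >= n3) continue;
              for (int p2 = 0; p2 < n2; ++p2) {
                const int s2 = p2 - q * a2;
                if (s2 < 0 || s2 >= n2) continue;
                for (int p1 = 0; p1 < n1; ++p1) {
                  const int s1 = p1 - q * a1;
                  if (s1 < 0 || s1 >= n1) continue;
                  const double g =
                      Gc[p1 + n1 * (p2 + static_cast<R_xlen_t>(n2) * p3)];
                  const R_xlen_t si =
                      s1 + n1 * (s2 + static_cast<R_xlen_t>(n2) * s3);
                  acc_w += g * Xc[si];
                  GXc[si] += g * wv;
                }
              }
            }
            GWc[wi] += acc_w;
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
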