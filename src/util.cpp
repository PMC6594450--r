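#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on an n-d binary grid (dims has length 2 or
// 3); `offsets` holds one neighbour offset per row. Returns 0 for background
// and 1..K component labels in first-encounter scan order.

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   IntegerMatrix offsets) {
  const int nd = dims.size();
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dims[d - 1];
  std::vector<R_xlen_t> stack;
  std::vector<int> coord(nd), nb(nd);
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || labels[start] != 0) continue;
    labels[start] = ++next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      R_xlen_t rem = cur;
      for (int d = nd - 1; d >= 0; --d) {
        coord[d] = static_cast<int>(rem / stride[d]);
        rem %= stride[d];
      }
      for (int o = 0; o < offsets.nrow(); ++o) {
        bool ok = true;
        R_xlen_t ni = 0;
        for (int d = 0; d < nd; ++d) {
          nb[d] = coord[d] + offsets(o, d);
          if (nb[d] < 0 || nb[d] >= dims[d]) {
            ok = false;
            break;
          }
          ni += nb[d] * stride[d];
        }
        if (ok && mask[ni] != 0 && labels[ni] == 0) {
          labels[ni] = next_label;
          stack.push_back(ni);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Affine resampling of a 2D multi-channel image: the value of output pixel p
// (0-based) is taken from input location M %*% p + v. interp 0 = nearest,
// 1 = bilinear; samples outside the grid read as `fill`.

// [[Rcpp::export]]
NumericVector cpp_warp2d(NumericVector x, NumericMatrix M, NumericVector v,
                         int interp, double fill) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], ci = xd[2];
  const R_xlen_t plane = static_cast<R_xlen_t>(n1) * n2;
  NumericVector y(plane * ci);
  y.attr("dim") = IntegerVector::create(n1, n2, ci);
  const double *X = x.begin();
  double *Y = y.begin();
  for (int p2 = 0; p2 < n2; ++p2)
    for (int p1 = 0; p1 < n1; ++p1) {
      const double s1 = M(0, 0) * p1 + M(0, 1) * p2 + v[0];
      const double s2 = M(1, 0) * p1 + M(1, 1) * p2 + v[1];
      const R_xlen_t pi = p1 + static_cast<R_xlen_t>(p2) * n1;
      if (interp == 0) {
        const int i1 = static_cast<int>(std::lround(s1));
        const int i2 = static_cast<int>(std::lround(s2));
        for (int c = 0; c < ci; ++c)
          Y[pi + c * plane] =
              (i1 < 0 || i1 >= n1 || i2 < 0 || i2 >= n2)
                  ? fill
                  : X[i1 + static_cast<R_xlen_t>(i2) * n1 + c * plane];
      } else {
        const int f1 = static_cast<int>(std::floor(s1));
        const int f2 = static_cast<int>(std::floor(s2));
        const double t1 = s1 - f1, t2 = s2 - f2;
        for (int c = 0; c < ci; ++c) {
          double acc = 0.0;
          for (int b2 = 0; b2 <= 1; ++b2)
            for (int b1 = 0; b1 <= 1; ++b1) {
              const int i1 = f1 + b1, i2 = f2 + b2;
              const double wgt =
                  (b1 ? t1 : 1.0 - t1) * (b2 ? t2 : 1.0 - t2);
              const double val =
                  (i1 < 0 || i1 >= n1 || i2 < 0 || i2 >= n2)
                      ? fill
                      : X[i1 + static_cast<R_xlen_t>(i2) * n1 + c * plane];
              acc += wgt * val;
            }
          Y[pi + c * plane] = acc;
        }
      }
    }
  return y;
}

// Average pooling by factor 2 on each spatial axis of (n1, n2, n3, c);
// partial boundary windows average over the cells actually present.

// [[Rcpp::export]]
NumericVector cpp_avgpool3d(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], ci = xd[3];
  const int m1 = (n1 + 1) / 2, m2 = (n2 + 1) / 2, m3 = (n3 + 1) / 2;
  const R_xlen_t vin = static_cast<R_xlen_t>(n1) * n2 * n3;
  const R_xlen_t vout = static_cast<R_xlen_t>(m1) * m2 * m3;
  NumericVector y(vout * ci);
  y.attr("dim") = IntegerVector::create(m1, m2, m3, ci);
  const double *X = x.begin();
  double *Y = y.begin();
  for (int c = 0; c < ci; ++c)
    for (int p3 = 0; p3 < m3; ++p3)
      for (int p2 = 0; p2 < m2; ++p2)
        for (int p1 = 0; p1 < m1; ++p1) {
          double acc = 0.0;
          int cnt = 0;
          for (int b3 = 0; b3 <= 1; ++b3)
            for (int b2 = 0; b2 <= 1; ++b2)
              for (int b1 = 0; b1 <= 1; ++b1) {
                const int i1 = 2 * p1 + b1, i2 = 2 * p2 + b2, i3 = 2 * p3 + b3;
                if (i1 >= n1 || i2 >= n2 || i3 >= n3) continue;
                acc += X[i1 + n1 * (i2 + static_cast<R_xlen_t>(n2) * i3) +
                         c * vin];
                ++cnt;
              }
          Y[p1 + m1 * (p2 + static_cast<R_xlen_t>(m2) * p3) + c * vout] =
              acc / cnt;
        }
  return y;
}

static inline void lin_coef(int out_i, int n_out, int n_in, int *i0, int *i1,
                            double *t) {
  // align-centers mapping from output to input coordinates
  const double s = (n_out == 1) ? 0.0
                                : (out_i + 0.5) * (static_cast<double>(n_in) /
                                                   n_out) -
                                      0.5;
  double f = std::floor(s);
  *t = s - f;
  *i0 = static_cast<int>(f);
  *i1 = *i0 + 1;
  if (*i0 < 0) { *i0 = 0; }
  if (*i1 > n_in - 1) { *i1 = n_in - 1; }
  if (*i0 > n_in - 1) { *i0 = n_in - 1; }
}

// Trilinear upsampling of (m1, m2, m3, c) to the spatial extent out_dims.

// [[Rcpp::export]]
NumericVector cpp_upsample3d(NumericVector x, IntegerVector out_dims) {
  IntegerVector xd = x.attr("dim");
  const int m1 = xd[0], m2 = xd[1], m3 = xd[2], ci = xd[3];
  const int n1 = out_dims[0], n2 = out_dims[1], n3 = out_dims[2];
  const R_xlen_t vin = static_cast<R_xlen_t>(m1) * m2 * m3;
  const R_xlen_t vout = static_cast<R_xlen_t>(n1) * n2 * n3;
  NumericVector y(vout * ci);
  y.attr("dim") = IntegerVector::create(n1, n2, n3, ci);
  const double *X = x.begin();
  double *Y = y.begin();
  for (int p3 = 0; p3 < n3; ++p3) {
    int a0, a1; double t3; lin_coef(p3, n3, m3, &a0, &a1, &t3);
    for (int p2 = 0; p2 < n2; ++p2) {
      int b0, b1; double t2; lin_coef(p2, n2, m2, &b0, &b1, &t2);
      for (int p1 = 0; p1 < n1; ++p1) {
        int c0, c1; double t1; lin_coef(p1, n1, m1, &c0, &c1, &t1);
        for (int c = 0; c < ci; ++c) {
          const double *Xc = X + c * vin;
          double acc = 0.0;
          for (int u3 = 0; u3 <= 1; ++u3)
            for (int u2 = 0; u2 <= 1; ++u2)
              for (int u1 = 0; u1 <= 1; ++u1) {
                const int i1 = u1 ? c1 : c0;
                const int i2 = u2 ? b1 : b0;
                const int i3 = u3 ? a1 : a0;
                const double wgt = (u1 ? t1 : 1 - t1) * (u2 ? t2 : 1 - t2) *
                                   (u3 ? t3 : 1 - t3);
                acc += wgt *
                       Xc[i1 + m1 * (i2 + static_cast<R_xlen_t>(m2) * i3)];
              }
          Y[p1 + n1 * (p2 + static_cast<R_xlen_t>(n2) * p3) + c * vout] = acc;
        }
      }
    }
  }
  return y;
}

// Adjoint of cpp_upsample3d: scatter output-space gradients back to the
// low-resolution grid with the same trilinear weights.

// [[Rcpp::export]]
NumericVector cpp_upsample3d_grad(NumericVector gy, IntegerVector in_dims) {
  IntegerVector gd = gy.attr("dim");
  const int n1 = gd[0], n2 = gd[1], n3 = gd[2], ci = gd[3];
  const int m1 = in_dims[0], m2 = in_dims[1], m3 = in_dims[2];
  const R_xlen_t vin = static_cast<R_xlen_t>(m1) * m2 * m3;
  const R_xlen_t vout = static_cast<R_xlen_t>(n1) * n2 * n3;
  NumericVector gx(vin * ci);
  gx.attr("dim") = IntegerVector::create(m1, m2, m3, ci);
  const double *GY = gy.begin();
  double *GX = gx.begin();
  for (int p3 = 0; p3 < n3; ++p3) {
    int a0, a1; double t3; lin_coef(p3, n3, m3, &a0, &a1, &t3);
    for (int p2 = 0; p2 < n2; ++p2) {
      int b0, b1; double t2; lin_coef(p2, n2, m2, &b0, &b1, &t2);
      for (int p1 = 0; p1 < n1; ++p1) {
        int c0, c1; double t1; lin_coef(p1, n1, m1, &c0, &c1, &t1);
        for (int c = 0; c < ci; ++c) {
          const double g =
              GY[p1 + n1 * (p2 + static_cast<R_xlen_t>(n2) * p3) + c * vout];
          double *GXc = GX + c * vin;
          for (int u3 = 0; u3 <= 1; ++u3)
            for (int u2 = 0; u2 <= 1; ++u2)
              for (int u1 = 0; u1 <= 1; ++u1) {
                const int i1 = u1 ? c1 : c0;
                const int i2 = u2 ? b1 : b0;
                const int i3 = u3 ? a1 : a0;
                const double wgt = (u1 ? t1 : 1 - t1) * (u2 ? t2 : 1 - t2) *
                                   (u3 ? t3 : 1 - t3);
                GXc[i1 + m1 * (i2 + static_cast<R_xlen_t>(m2) * i3)] +=
                    wgt * g;
              }
        }
      }
    }
  }
  return gx;
}
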