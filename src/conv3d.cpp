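// 3x3x3 same-padding, stride-1 convolution and average pooling for the
// compact volumetric CNN. Feature maps are (nvox, C, B) arrays with voxels
// in x-fastest order for spatial dims; weights are (27*Cin, Cout) with
// column index ci + Cin*k, k enumerating the 3x3x3 offsets x-fastest.
// im2col + BLAS keeps training CPU-friendly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::imat neighbor_index(const IntegerVector &dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nvox = nx * ny * nz;
  arma::imat idx(nvox, 27);
  int v = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++v) {
        int k = 0;
        for (int oz = -1; oz <= 1; ++oz)
          for (int oy = -1; oy <= 1; ++oy)
            for (int ox = -1; ox <= 1; ++ox, ++k) {
              int x2 = x + ox, y2 = y + oy, z2 = z + oz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                idx(v, k) = -1;
              else
                idx(v, k) = x2 + nx * (y2 + ny * z2);
            }
      }
  return idx;
}

static void im2col(const double *x, const arma::imat &idx, int cin,
                   arma::mat &col) {
  int nvox = idx.n_rows;
  for (int k = 0; k < 27; ++k)
    for (int c = 0; c < cin; ++c) {
      double *dst = col.colptr(c + cin * k);
      const double *src = x + (size_t)nvox * c;
      for (int v = 0; v < nvox; ++v) {
        int j = idx(v, k);
        dst[v] = (j < 0) ? 0.0 : src[j];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector dims,
                            NumericMatrix w) {
  IntegerVector xd = x.attr("dim");
  int nvox = xd[0], cin = xd[1], B = xd[2];
  int cout = w.ncol();
  arma::mat W(w.begin(), w.nrow(), cout, false);
  NumericVector out((size_t)nvox * cout * B);
  arma::imat idx = neighbor_index(dims);
  arma::mat col(nvox, 27 * cin);
  for (int b = 0; b < B; ++b) {
    im2col(&x[(size_t)nvox * cin * b], idx, cin, col);
    arma::mat y(&out[(size_t)nvox * cout * b], nvox, cout, false, true);
    y = col * W;
  }
  out.attr("dim") = IntegerVector::create(nvox, cout, B);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector dy, IntegerVector dims,
                   NumericMatrix w, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  int nvox = xd[0], cin = xd[1], B = xd[2];
  int cout = w.ncol();
  arma::mat W(w.begin(), w.nrow(), cout, false);
  arma::imat idx = neighbor_index(dims);
  arma::mat col(nvox, 27 * cin);
  arma::mat dW(27 * cin, cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)nvox * cin * B);
    dx.attr("dim") = IntegerVector::create(nvox, cin, B);
  }
  for (int b = 0; b < B; ++b) {
    im2col(&x[(size_t)nvox * cin * b], idx, cin, col);
    arma::mat dY((double *)&dy[(size_t)nvox * cout * b], nvox, cout, false);
    dW += col.t() * dY;
    if (need_dx) {
      arma::mat dcol = dY * W.t();
      double *dxb = &dx[(size_t)nvox * cin * b];
      for (int k = 0; k < 27; ++k)
        for (int c = 0; c < cin; ++c) {
          const double *src = dcol.colptr(c + cin * k);
          double *dst = dxb + (size_t)nvox * c;
          for (int v = 0; v < nvox; ++v) {
            int j = idx(v, k);
            if (j >= 0) dst[j] += src[v];
          }
        }
    }
  }
  NumericMatrix dWout(27 * cin, cout);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  if (need_dx) return List::create(_["dx"] = dx, _["dw"] = dWout);
  return List::create(_["dw"] = dWout);
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_fw(NumericVector x, IntegerVector dims, int f) {
  IntegerVector xd = x.attr("dim");
  int nvox = xd[0], C = xd[1], B = xd[2];
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = nx / f, my = ny / f, mz = nz / f;
  int mvox = mx * my * mz;
  double inv = 1.0 / (f * f * f);
  NumericVector out((size_t)mvox * C * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double *src = &x[(size_t)nvox * (c + (size_t)C * b)];
      double *dst = &out[(size_t)mvox * (c + (size_t)C * b)];
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int xx = 0; xx < nx; ++xx) {
            int o = (xx / f) + mx * ((y / f) + my * (z / f));
            dst[o] += src[xx + nx * (y + ny * z)] * inv;
          }
    }
  out.attr("dim") = IntegerVector::create(mvox, C, B);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bw(NumericVector dy, IntegerVector dims, int f) {
  // dims are the *input* spatial dims of the forward pass
  IntegerVector yd = dy.attr("dim");
  int C = yd[1], B = yd[2];
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = nx / f, my = ny / f, mz = nz / f;
  int nvox = nx * ny * nz, mvox = mx * my * mz;
  double inv = 1.0 / (f * f * f);
  NumericVector dx((size_t)nvox * C * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double *src = &dy[(size_t)mvox * (c + (size_t)C * b)];
      double *dst = &dx[(size_t)nvox * (c + (size_t)C * b)];
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int xx = 0; xx < nx; ++xx) {
            int o = (xx / f) + mx * ((y / f) + my * (z / f));
            dst[xx + nx * (y + ny * z)] = src[o] * inv;
          }
    }
  dx.attr("dim") = IntegerVector::create(nvox, C, B);
  return dx;
}
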