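// Dense 3-D convolution and max-pooling kernels for the small actor/critic
// networks. Arrays follow R's column-major layout:
//   x: (nx, ny, nz, ci), w: (k, k, k, ci, co), y: (nx, ny, nz, co).
// "Same" spatial extent via zero padding; for even filter edges the extra
// cell pads the high side of each axis (pad_lo = (k-1)/2, pad_hi = k/2).
// Loops are tap-major: for each filter tap the whole (clipped) volume is
// shifted and accumulated with a contiguous inner loop over x.

#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t idx4(int i, int j, int k, int c, int nx, int ny,
                            int nz) {
  return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * (k + (R_xlen_t)nz * c));
}

// [[Rcpp::export]]
NumericVector conv3d_forward(NumericVector x, NumericVector w,
                             NumericVector bias, IntegerVector xdim,
                             int kedge) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci = xdim[3];
  const int co = bias.size();
  const int plo = (kedge - 1) / 2;
  NumericVector y(R_xlen_t(nx) * ny * nz * co);
  const double *X = x.begin(), *W = w.begin(), *B = bias.begin();
  double *Y = y.begin();
  for (int oc = 0; oc < co; ++oc) {
    double *yc = Y + idx4(0, 0, 0, oc, nx, ny, nz);
    const double bb = B[oc];
    for (R_xlen_t i = 0, n = (R_xlen_t)nx * ny * nz; i < n; ++i) yc[i] = bb;
    for (int c = 0; c < ci; ++c) {
      const double *xc = X + idx4(0, 0, 0, c, nx, ny, nz);
      for (int kz = 0; kz < kedge; ++kz) {
        const int dz = kz - plo;
        const int oz0 = std::max(0, -dz), oz1 = std::min(nz, nz - dz);
        for (int ky = 0; ky < kedge; ++ky) {
          const int dy_ = ky - plo;
          const int oy0 = std::max(0, -dy_), oy1 = std::min(ny, ny - dy_);
          for (int kx = 0; kx < kedge; ++kx) {
            const int dx_ = kx - plo;
            const int ox0 = std::max(0, -dx_), ox1 = std::min(nx, nx - dx_);
            const double wv =
                W[kx + (R_xlen_t)kedge *
                          (ky + (R_xlen_t)kedge *
                                    (kz + (R_xlen_t)kedge * (c + (R_xlen_t)ci * oc)))];
            if (wv == 0.0) continue;
            for (int oz = oz0; oz < oz1; ++oz)
              for (int oy = oy0; oy < oy1; ++oy) {
                double *yrow = yc + (R_xlen_t)nx * (oy + (R_xlen_t)ny * oz);
                const double *xrow =
                    xc + dx_ + (R_xlen_t)nx * ((oy + dy_) + (R_xlen_t)ny * (oz + dz));
                for (int ox = ox0; ox < ox1; ++ox) yrow[ox] += wv * xrow[ox];
              }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(nx, ny, nz, co);
  return y;
}

// [[Rcpp::export]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     IntegerVector xdim, int kedge, int co) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci = xdim[3];
  const int plo = (kedge - 1) / 2;
  NumericVector dx(x.size()), dw(w.size()), db(co);
  const double *X = x.begin(), *W = w.begin(), *DY = dy.begin();
  double *DX = dx.begin(), *DW = dw.begin(), *DB = db.begin();
  for (int oc = 0; oc < co; ++oc) {
    const double *gc = DY + idx4(0, 0, 0, oc, nx, ny, nz);
    double acc = 0.0;
    for (R_xlen_t i = 0, n = (R_xlen_t)nx * ny * nz; i < n; ++i) acc += gc[i];
    DB[oc] += acc;
    for (int c = 0; c < ci; ++c) {
      const double *xc = X + idx4(0, 0, 0, c, nx, ny, nz);
      double *dxc = DX + idx4(0, 0, 0, c, nx, ny, nz);
      for (int kz = 0; kz < kedge; ++kz) {
        const int dz = kz - plo;
        const int oz0 = std::max(0, -dz), oz1 = std::min(nz, nz - dz);
        for (int ky = 0; ky < kedge; ++ky) {
          const int dy_ = ky - plo;
          const int oy0 = std::max(0, -dy_), oy1 = std::min(ny, ny - dy_);
          for (int kx = 0; kx < kedge; ++kx) {
            const int dx_ = kx - plo;
            const int ox0 = std::max(0, -dx_), ox1 = std::min(nx, nx - dx_);
            const R_xlen_t wi =
                kx + (R_xlen_t)kedge *
                         (ky + (R_xlen_t)kedge *
                                   (kz + (R_xlen_t)kedge * (c + (R_xlen_t)ci * oc)));
            const double wv = W[wi];
            double wacc = 0.0;
            for (int oz = oz0; oz < oz1; ++oz)
              for (int oy = oy0; oy < oy1; ++oy) {
                const double *grow = gc + (R_xlen_t)nx * (oy + (R_xlen_t)ny * oz);
                const double *xrow =
                    xc + dx_ + (R_xlen_t)nx * ((oy + dy_) + (R_xlen_t)ny * (oz + dz));
                double *dxrow =
                    dxc + dx_ + (R_xlen_t)nx * ((oy + dy_) + (R_xlen_t)ny * (oz + dz));
                for (int ox = ox0; ox < ox1; ++ox) {
                  wacc += grow[ox] * xrow[ox];
                  dxrow[ox] += grow[ox] * wv;
                }
              }
            DW[wi] += wacc;
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = IntegerVector::create(kedge, kedge, kedge, ci, co);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export]]
List maxpool3d_forward(NumericVector x, IntegerVector xdim, int pool) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  const int mx = nx / pool, my = ny / pool, mz = nz / pool;
  NumericVector y(R_xlen_t(mx) * my * mz * nc);
  IntegerVector amax(y.size());
  const double *X = x.begin();
  double *Y = y.begin();
  int *A = amax.begin();
  for (int c = 0; c < nc; ++c)
    for (int oz = 0; oz < mz; ++oz)
      for (int oy = 0; oy < my; ++oy)
        for (int ox = 0; ox < mx; ++ox) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int kz = 0; kz < pool; ++kz)
            for (int ky = 0; ky < pool; ++ky)
              for (int kx = 0; kx < pool; ++kx) {
                R_xlen_t ii = idx4(ox * pool + kx, oy * pool + ky,
                                   oz * pool + kz, c, nx, ny, nz);
                if (X[ii] > best) { best = X[ii]; besti = ii; }
              }
          R_xlen_t oi = idx4(ox, oy, oz, c, mx, my, mz);
          Y[oi] = best;
          A[oi] = (int)besti;
        }
  y.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return List::create(Named("y") = y, Named("argmax") = amax);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward(NumericVector dy, IntegerVector argmax,
                                 IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  const double *DY = dy.begin();
  const int *A = argmax.begin();
  double *DX = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) DX[A[i]] += DY[i];
  dx.attr("dim") = xdim;
  return dx;
}
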