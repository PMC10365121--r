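// Low-level volumetric kernels: 3D convolutions (im2col + GEMM), pooling,
// trilinear resizing with exact adjoint, affine resampling, connected
// components and binary morphology. Arrays are column-major with dim
// (X, Y, Z, C); weight matrices are (Cout, k^3 * Cin) with row index
// r = kx + k*(ky + k*kz) + k^3*ci.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int X, int Y) {
  return x + X * (y + Y * z);
}

// ---------------------------------------------------------------------------
// im2col / col2im in (N, k^3*C) layout: stride-1 voxel access, GEMM-ready
// ---------------------------------------------------------------------------

static arma::mat im2col3(const double* x, int X, int Y, int Z, int C,
                         int k) {
  const int k3 = k * k * k, N = X * Y * Z, p = k / 2;
  arma::mat col(N, (size_t)k3 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)N * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          size_t r = kx + k * (ky + k * kz) + (size_t)k3 * c;
          double* cr = col.colptr(r);
          for (int z = 0; z < Z; ++z) {
            int iz = z + kz - p;
            if (iz < 0 || iz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              int iy = y + ky - p;
              if (iy < 0 || iy >= Y) continue;
              int x0 = std::max(0, p - kx), x1 = std::min(X, X + p - kx);
              const double* src = xc + idx3(x0 + kx - p, iy, iz, X, Y);
              double* dst = cr + idx3(x0, y, z, X, Y);
              std::copy(src, src + (x1 - x0), dst);
            }
          }
        }
  }
  return col;
}

static void col2im3(const arma::mat& col, double* x, int X, int Y, int Z,
                    int C, int k) {
  const int k3 = k * k * k, N = X * Y * Z, p = k / 2;
  std::fill(x, x + (size_t)N * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)N * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          size_t r = kx + k * (ky + k * kz) + (size_t)k3 * c;
          const double* cr = col.colptr(r);
          for (int z = 0; z < Z; ++z) {
            int iz = z + kz - p;
            if (iz < 0 || iz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              int iy = y + ky - p;
              if (iy < 0 || iy >= Y) continue;
              int x0 = std::max(0, p - kx), x1 = std::min(X, X + p - kx);
              double* dst = xc + idx3(x0 + kx - p, iy, iz, X, Y);
              const double* src = cr + idx3(x0, y, z, X, Y);
              for (int i = 0; i < x1 - x0; ++i) dst[i] += src[i];
            }
          }
        }
  }
}

static NumericVector from_nc(const arma::mat& m, int X, int Y, int Z,
                             int C) {
  // m is (N, C): already the (X,Y,Z,C) array layout
  NumericVector out(m.memptr(), m.memptr() + m.n_elem);
  out.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix W, NumericVector b, int k) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Co = W.nrow(), N = X * Y * Z;
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat out;
  if (k == 1) {
    arma::mat xm(x.begin(), N, C, false);
    out = xm * Wm.t();
  } else {
    arma::mat col = im2col3(x.begin(), X, Y, Z, C, k);
    out = col * Wm.t();
  }
  for (int c = 0; c < Co; ++c) out.col(c) += b[c];
  return from_nc(out, X, Y, Z, Co);
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector dims, NumericVector dy,
                   NumericMatrix W, int k) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Co = W.nrow(), N = X * Y * Z;
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat dY(dy.begin(), N, Co, false);
  arma::vec db = arma::sum(dY, 0).t();
  NumericVector dx((size_t)N * C);
  arma::mat dW;
  if (k == 1) {
    arma::mat xm(x.begin(), N, C, false);
    dW = dY.t() * xm;
    arma::mat dxm(dx.begin(), N, C, false);
    dxm = dY * Wm;
  } else {
    arma::mat col = im2col3(x.begin(), X, Y, Z, C, k);
    dW = dY.t() * col;
    arma::mat dcol = dY * Wm;
    col2im3(dcol, dx.begin(), X, Y, Z, C, k);
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW),
                      _["db"] = wrap(db));
}

// ---------------------------------------------------------------------------
// stride-2 conv, k = 3, pad = 1 (duality partner of the transpose conv)
// out dim = floor((d - 1) / 2) + 1  (= d/2 for even d)
// ---------------------------------------------------------------------------

static arma::mat im2col3_s2(const double* x, int X, int Y, int Z, int C,
                            int Xo, int Yo, int Zo) {
  const int k = 3, k3 = 27;
  size_t No = (size_t)Xo * Yo * Zo;
  arma::mat col(No, (size_t)k3 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)X * Y * Z * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          size_t r = kx + k * (ky + k * kz) + (size_t)k3 * c;
          double* cr = col.colptr(r);
          for (int z = 0; z < Zo; ++z) {
            int iz = 2 * z + kz - 1;
            if (iz < 0 || iz >= Z) continue;
            for (int y = 0; y < Yo; ++y) {
              int iy = 2 * y + ky - 1;
              if (iy < 0 || iy >= Y) continue;
              for (int xo = 0; xo < Xo; ++xo) {
                int ix = 2 * xo + kx - 1;
                if (ix < 0 || ix >= X) continue;
                cr[idx3(xo, y, z, Xo, Yo)] = xc[idx3(ix, iy, iz, X, Y)];
              }
            }
          }
        }
  }
  return col;
}

static void col2im3_s2(const arma::mat& col, double* x, int X, int Y,
                       int Z, int C, int Xo, int Yo, int Zo) {
  const int k = 3, k3 = 27;
  std::fill(x, x + (size_t)X * Y * Z * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)X * Y * Z * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          size_t r = kx + k * (ky + k * kz) + (size_t)k3 * c;
          const double* cr = col.colptr(r);
          for (int z = 0; z < Zo; ++z) {
            int iz = 2 * z + kz - 1;
            if (iz < 0 || iz >= Z) continue;
            for (int y = 0; y < Yo; ++y) {
              int iy = 2 * y + ky - 1;
              if (iy < 0 || iy >= Y) continue;
              for (int xo = 0; xo < Xo; ++xo) {
                int ix = 2 * xo + kx - 1;
                if (ix < 0 || ix >= X) continue;
                xc[idx3(ix, iy, iz, X, Y)] += cr[idx3(xo, y, z, Xo, Yo)];
              }
            }
          }
        }
  }
}

static inline int outdim_s2(int d) { return (d - 1) / 2 + 1; }

// [[Rcpp::export]]
NumericVector cpp_conv3s2_fwd(NumericVector x, IntegerVector dims,
                              NumericMatrix W, NumericVector b) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Xo = outdim_s2(X), Yo = outdim_s2(Y), Zo = outdim_s2(Z);
  int Co = W.nrow();
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat col = im2col3_s2(x.begin(), X, Y, Z, C, Xo, Yo, Zo);
  arma::mat out = col * Wm.t();
  for (int c = 0; c < Co; ++c) out.col(c) += b[c];
  return from_nc(out, Xo, Yo, Zo, Co);
}

// [[Rcpp::export]]
NumericVector cpp_conv3s2_bwd_data(NumericVector dy, IntegerVector odims,
                                   NumericMatrix W, IntegerVector idims) {
  // odims: dims of the stride-2 conv output (coarse); idims: fine + Cin
  int X = idims[0], Y = idims[1], Z = idims[2], C = idims[3];
  int Xo = odims[0], Yo = odims[1], Zo = odims[2], Co = odims[3];
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat dY(dy.begin(), (size_t)Xo * Yo * Zo, Co, false);
  arma::mat dcol = dY * Wm;
  NumericVector dx((size_t)X * Y * Z * C);
  col2im3_s2(dcol, dx.begin(), X, Y, Z, C, Xo, Yo, Zo);
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return dx;
}

// [[Rcpp::export]]
List cpp_conv3s2_bwd_w(NumericVector x, IntegerVector dims,
                       NumericVector dy, IntegerVector odims) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Xo = odims[0], Yo = odims[1], Zo = odims[2], Co = odims[3];
  arma::mat dY(dy.begin(), (size_t)Xo * Yo * Zo, Co, false);
  arma::mat col = im2col3_s2(x.begin(), X, Y, Z, C, Xo, Yo, Zo);
  arma::mat dW = dY.t() * col;
  arma::vec db = arma::sum(dY, 0).t();
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db));
}


// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims, int k) {
  arma::mat col = im2col3(x.begin(), dims[0], dims[1], dims[2], dims[3], k);
  return wrap(col);
}

// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix col, IntegerVector dims, int k) {
  arma::mat cm(col.begin(), col.nrow(), col.ncol(), false);
  NumericVector dx((size_t)dims[0] * dims[1] * dims[2] * dims[3]);
  col2im3(cm, dx.begin(), dims[0], dims[1], dims[2], dims[3], k);
  dx.attr("dim") = dims;
  return dx;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col3_s2(NumericVector x, IntegerVector dims,
                             IntegerVector odims) {
  arma::mat col = im2col3_s2(x.begin(), dims[0], dims[1], dims[2], dims[3],
                             odims[0], odims[1], odims[2]);
  return wrap(col);
}


// ---------------------------------------------------------------------------
// direct 3D convolution (shifted-axpy): for the small channel counts used
// at train scale the operands stay cache-resident, beating im2col + GEMM
// ---------------------------------------------------------------------------

// iterate the valid output range for one kernel offset, applying f(dst, src, len)
template <class F>
static inline void offset_runs(int X, int Y, int Z, int kx, int ky, int kz,
                               F f) {
  const int p = 1;
  int x0 = std::max(0, p - kx), x1 = std::min(X, X + p - kx);
  if (x1 <= x0) return;
  for (int z = 0; z < Z; ++z) {
    int iz = z + kz - p;
    if (iz < 0 || iz >= Z) continue;
    for (int y = 0; y < Y; ++y) {
      int iy = y + ky - p;
      if (iy < 0 || iy >= Y) continue;
      f(idx3(x0, y, z, X, Y), idx3(x0 + kx - p, iy, iz, X, Y), x1 - x0);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix W, NumericVector b) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Co = W.nrow();
  size_t N = (size_t)X * Y * Z;
  NumericVector out(N * Co);
  for (int co = 0; co < Co; ++co) {
    double* yc = out.begin() + N * co;
    std::fill(yc, yc + N, b[co]);
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + N * c;
      for (int kz = 0; kz < 3; ++kz)
        for (int ky = 0; ky < 3; ++ky)
          for (int kx = 0; kx < 3; ++kx) {
            double w = W(co, kx + 3 * (ky + 3 * kz) + 27 * c);
            if (w == 0.0) continue;
            offset_runs(X, Y, Z, kx, ky, kz,
                        [&](int o, int i, int len) {
                          const double* src = xc + i;
                          double* dst = yc + o;
                          for (int t = 0; t < len; ++t) dst[t] += w * src[t];
                        });
          }
    }
  }
  out.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, NumericVector dy,
                    NumericMatrix W, bool need_dx) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Co = W.nrow();
  size_t N = (size_t)X * Y * Z;
  NumericMatrix dW(Co, 27 * C);
  NumericVector db(Co);
  NumericVector dx(need_dx ? N * C : 0);
  for (int co = 0; co < Co; ++co) {
    const double* gc = dy.begin() + N * co;
    double s = 0;
    for (size_t t = 0; t < N; ++t) s += gc[t];
    db[co] = s;
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + N * c;
      double* dxc = need_dx ? dx.begin() + N * c : nullptr;
      for (int kz = 0; kz < 3; ++kz)
        for (int ky = 0; ky < 3; ++ky)
          for (int kx = 0; kx < 3; ++kx) {
            int r = kx + 3 * (ky + 3 * kz) + 27 * c;
            double w = W(co, r);
            double acc = 0;
            offset_runs(X, Y, Z, kx, ky, kz,
                        [&](int o, int i, int len) {
                          const double* g = gc + o;
                          const double* xs = xc + i;
                          double a = 0;
                          for (int t = 0; t < len; ++t) a += g[t] * xs[t];
                          acc += a;
                          if (dxc) {
                            double* d = dxc + i;
                            for (int t = 0; t < len; ++t) d[t] += w * g[t];
                          }
                        });
            dW(co, r) = acc;
          }
    }
  }
  if (need_dx) dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2x2x2 max pooling, stride 2 (even dims required, checked in R)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector dims) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  size_t No = (size_t)Xo * Yo * Zo;
  NumericVector y(No * C);
  IntegerVector arg(No * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)X * Y * Z * c;
    double* yc = y.begin() + No * c;
    int* ac = arg.begin() + No * c;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          double best = -1e300;
          int bidx = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int i = idx3(2 * xx + dx, 2 * yy + dy, 2 * z + dz, X, Y);
                if (xc[i] > best) { best = xc[i]; bidx = i; }
              }
          int o = idx3(xx, yy, z, Xo, Yo);
          yc[o] = best;
          ac[o] = bidx;
        }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector arg,
                               IntegerVector dims) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  size_t N = (size_t)X * Y * Z;
  size_t No = dy.size() / C;
  NumericVector dx(N * C);
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.begin() + N * c;
    const double* dyc = dy.begin() + No * c;
    const int* ac = arg.begin() + No * c;
    for (size_t o = 0; o < No; ++o) dxc[ac[o]] += dyc[o];
  }
  dx.attr("dim") = dims;
  return dx;
}

// ---------------------------------------------------------------------------
// 3x3x3 average pooling, stride 2, same padding, edge-renormalised
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_avgpool3s2_fwd(NumericVector x, IntegerVector dims) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Xo = outdim_s2(X), Yo = outdim_s2(Y), Zo = outdim_s2(Z);
  size_t No = (size_t)Xo * Yo * Zo;
  NumericVector y(No * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)X * Y * Z * c;
    double* yc = y.begin() + No * c;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          double s = 0.0;
          int n = 0;
          for (int dz = -1; dz <= 1; ++dz) {
            int iz = 2 * z + dz;
            if (iz < 0 || iz >= Z) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int iy = 2 * yy + dy;
              if (iy < 0 || iy >= Y) continue;
              for (int dx = -1; dx <= 1; ++dx) {
                int ix = 2 * xx + dx;
                if (ix < 0 || ix >= X) continue;
                s += xc[idx3(ix, iy, iz, X, Y)];
                ++n;
              }
            }
          }
          yc[idx3(xx, yy, z, Xo, Yo)] = s / n;
        }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool3s2_bwd(NumericVector dy, IntegerVector dims) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Xo = outdim_s2(X), Yo = outdim_s2(Y), Zo = outdim_s2(Z);
  size_t N = (size_t)X * Y * Z, No = (size_t)Xo * Yo * Zo;
  NumericVector dx(N * C);
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.begin() + N * c;
    const double* dyc = dy.begin() + No * c;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          int n = 0;
          for (int dz = -1; dz <= 1; ++dz) {
            int iz = 2 * z + dz;
            if (iz < 0 || iz >= Z) continue;
            for (int dy2 = -1; dy2 <= 1; ++dy2) {
              int iy = 2 * yy + dy2;
              if (iy < 0 || iy >= Y) continue;
              for (int dx2 = -1; dx2 <= 1; ++dx2) {
                int ix = 2 * xx + dx2;
                if (ix < 0 || ix >= X) continue;
                ++n;
              }
            }
          }
          double g = dyc[idx3(xx, yy, z, Xo, Yo)] / n;
          for (int dz = -1; dz <= 1; ++dz) {
            int iz = 2 * z + dz;
            if (iz < 0 || iz >= Z) continue;
            for (int dy2 = -1; dy2 <= 1; ++dy2) {
              int iy = 2 * yy + dy2;
              if (iy < 0 || iy >= Y) continue;
              for (int dx2 = -1; dx2 <= 1; ++dx2) {
                int ix = 2 * xx + dx2;
                if (ix < 0 || ix >= X) continue;
                dxc[idx3(ix, iy, iz, X, Y)] += g;
              }
            }
          }
        }
  }
  dx.attr("dim") = dims;
  return dx;
}

// ---------------------------------------------------------------------------
// trilinear resize (half-pixel centre alignment) and its exact adjoint
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resize_tril(NumericVector x, IntegerVector dims,
                              IntegerVector odims, bool adjoint) {
  int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  int Xo = odims[0], Yo = odims[1], Zo = odims[2];
  size_t N = (size_t)X * Y * Z, No = (size_t)Xo * Yo * Zo;
  NumericVector out((adjoint ? N : No) * C);
  double sx = (double)X / Xo, sy = (double)Y / Yo, sz = (double)Z / Zo;
  for (int z = 0; z < Zo; ++z) {
    double fz = (z + 0.5) * sz - 0.5;
    int z0 = (int)std::floor(fz);
    double wz = fz - z0;
    int z0c = std::min(std::max(z0, 0), Z - 1);
    int z1c = std::min(std::max(z0 + 1, 0), Z - 1);
    for (int y = 0; y < Yo; ++y) {
      double fy = (y + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(fy);
      double wy = fy - y0;
      int y0c = std::min(std::max(y0, 0), Y - 1);
      int y1c = std::min(std::max(y0 + 1, 0), Y - 1);
      for (int xx = 0; xx < Xo; ++xx) {
        double fx = (xx + 0.5) * sx - 0.5;
        int x0 = (int)std::floor(fx);
        double wx = fx - x0;
        int x0c = std::min(std::max(x0, 0), X - 1);
        int x1c = std::min(std::max(x0 + 1, 0), X - 1);
        int corner[8] = {idx3(x0c, y0c, z0c, X, Y), idx3(x1c, y0c, z0c, X, Y),
                         idx3(x0c, y1c, z0c, X, Y), idx3(x1c, y1c, z0c, X, Y),
                         idx3(x0c, y0c, z1c, X, Y), idx3(x1c, y0c, z1c, X, Y),
                         idx3(x0c, y1c, z1c, X, Y), idx3(x1c, y1c, z1c, X, Y)};
        double wgt[8] = {(1 - wx) * (1 - wy) * (1 - wz),
                         wx * (1 - wy) * (1 - wz),
                         (1 - wx) * wy * (1 - wz),
                         wx * wy * (1 - wz),
                         (1 - wx) * (1 - wy) * wz,
                         wx * (1 - wy) * wz,
                         (1 - wx) * wy * wz,
                         wx * wy * wz};
        int o = idx3(xx, y, z, Xo, Yo);
        for (int c = 0; c < C; ++c) {
          if (!adjoint) {
            const double* xc = x.begin() + N * c;
            double v = 0;
            for (int j = 0; j < 8; ++j) v += wgt[j] * xc[corner[j]];
            out[No * c + o] = v;
          } else {
            double g = x[No * c + o];  // x holds dY in adjoint mode
            double* oc = out.begin() + N * c;
            for (int j = 0; j < 8; ++j) oc[corner[j]] += wgt[j] * g;
          }
        }
      }
    }
  }
  if (!adjoint)
    out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  else
    out.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return out;
}

// ---------------------------------------------------------------------------
// affine resampling of a single-channel volume: out(v) = in(A v + t)
// order 0 (nearest) or 1 (trilinear); zero fill outside
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector x, IntegerVector dims,
                                NumericMatrix A, NumericVector t,
                                IntegerVector odims, int order,
                                int clamp = 0) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  int Xo = odims[0], Yo = odims[1], Zo = odims[2];
  NumericVector out((size_t)Xo * Yo * Zo);
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int xx = 0; xx < Xo; ++xx) {
        double fx = A(0, 0) * xx + A(0, 1) * y + A(0, 2) * z + t[0];
        double fy = A(1, 0) * xx + A(1, 1) * y + A(1, 2) * z + t[1];
        double fz = A(2, 0) * xx + A(2, 1) * y + A(2, 2) * z + t[2];
        if (clamp) {
          fx = std::min(std::max(fx, 0.0), (double)X - 1);
          fy = std::min(std::max(fy, 0.0), (double)Y - 1);
          fz = std::min(std::max(fz, 0.0), (double)Z - 1);
        }
        double v = 0.0;
        if (order == 0) {
          int ix = (int)std::floor(fx + 0.5), iy = (int)std::floor(fy + 0.5),
              iz = (int)std::floor(fz + 0.5);
          if (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 && iz < Z)
            v = x[idx3(ix, iy, iz, X, Y)];
        } else {
          int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
              z0 = (int)std::floor(fz);
          double wx = fx - x0, wy = fy - y0, wz = fz - z0;
          for (int dz = 0; dz <= 1; ++dz) {
            int iz = z0 + dz;
            if (iz < 0 || iz >= Z) continue;
            double wzz = dz ? wz : 1 - wz;
            for (int dy = 0; dy <= 1; ++dy) {
              int iy = y0 + dy;
              if (iy < 0 || iy >= Y) continue;
              double wyy = dy ? wy : 1 - wy;
              for (int dx = 0; dx <= 1; ++dx) {
                int ix = x0 + dx;
                if (ix < 0 || ix >= X) continue;
                double wxx = dx ? wx : 1 - wx;
                v += wxx * wyy * wzz * x[idx3(ix, iy, iz, X, Y)];
              }
            }
          }
        }
        out[idx3(xx, y, z, Xo, Yo)] = v;
      }
  out.attr("dim") = odims;
  return out;
}

// ---------------------------------------------------------------------------
// connected components (6/18/26) on a binary mask, BFS, deterministic order
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_cc_label(IntegerVector mask, IntegerVector dims,
                           int connectivity) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  size_t N = (size_t)X * Y * Z;
  IntegerVector lab(N);
  std::vector<int> stack;
  int next = 0;
  for (size_t s = 0; s < N; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int x = i % X, y = (i / X) % Y, z = i / (X * Y);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (ad == 0) continue;
            if (connectivity == 6 && ad > 1) continue;
            if (connectivity == 18 && ad > 2) continue;
            int nx = x + dx, ny = y + dy, nz = z + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
              continue;
            int j = idx3(nx, ny, nz, X, Y);
            if (mask[j] != 0 && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// binary morphology with a 3x3x3 cube (dilate / erode); closing = both
// ---------------------------------------------------------------------------

static void dilate3(const int* in, int* out, int X, int Y, int Z) {
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        int v = 0;
        for (int dz = -1; dz <= 1 && !v; ++dz) {
          int iz = z + dz;
          if (iz < 0 || iz >= Z) continue;
          for (int dy = -1; dy <= 1 && !v; ++dy) {
            int iy = y + dy;
            if (iy < 0 || iy >= Y) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int ix = x + dx;
              if (ix < 0 || ix >= X) continue;
              if (in[idx3(ix, iy, iz, X, Y)]) { v = 1; break; }
            }
          }
        }
        out[idx3(x, y, z, X, Y)] = v;
      }
}

static void erode3(const int* in, int* out, int X, int Y, int Z) {
  // voxels outside the volume count as foreground so closing does not
  // shrink objects touching the border
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        int v = 1;
        for (int dz = -1; dz <= 1 && v; ++dz) {
          int iz = z + dz;
          if (iz < 0 || iz >= Z) continue;
          for (int dy = -1; dy <= 1 && v; ++dy) {
            int iy = y + dy;
            if (iy < 0 || iy >= Y) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int ix = x + dx;
              if (ix < 0 || ix >= X) continue;
              if (!in[idx3(ix, iy, iz, X, Y)]) {
                v = 0;
                break;
              }
            }
          }
        }
        out[idx3(x, y, z, X, Y)] = v;
      }
}

// [[Rcpp::export]]
IntegerVector cpp_binary_close3(IntegerVector mask, IntegerVector dims) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  size_t N = (size_t)X * Y * Z;
  IntegerVector tmp(N), out(N);
  dilate3(mask.begin(), tmp.begin(), X, Y, Z);
  erode3(tmp.begin(), out.begin(), X, Y, Z);
  out.attr("dim") = dims;
  return out;
}
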