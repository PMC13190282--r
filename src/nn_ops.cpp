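// Dense 3D tensor kernels for the encoder-decoder network and volume
// utilities. Feature maps are (channels x voxels) matrices in x-fastest
// (column-major array) voxel order. Convolutions are 3x3x3 with padding 1,
// computed in single precision as 27 offset GEMMs against shifted input
// copies; shifted buffers are rebuilt in the backward pass rather than
// cached, trading FLOPs for memory so a whole training run stays small.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef arma::fmat FM;
typedef arma::fvec FV;

static FM to_f(const arma::mat& m) {
  return arma::conv_to<FM>::from(m);
}
static arma::mat to_d(const FM& m) {
  return arma::conv_to<arma::mat>::from(m);
}

// The 3x3x3 convolution is computed as a sum over the 27 kernel offsets of
// one GEMM each against a shifted copy of the input. Shifted copies are
// assembled with contiguous memcpy runs along x (the fastest axis), which is
// far more cache-friendly than materialising a full 27C x N im2col buffer.

// buf <- X shifted by (dx, dy, dz), zero-padded.
static void shifted_copy(const FM& X, int d, int h, int w, int dx, int dy,
                         int dz, FM& buf) {
  const int C = X.n_rows;
  buf.zeros();
  const int x0 = std::max(0, -dx), x1 = std::min(d, d - dx) - 1;
  const int y0 = std::max(0, -dy), y1 = std::min(h, h - dy) - 1;
  const int z0 = std::max(0, -dz), z1 = std::min(w, w - dz) - 1;
  if (x1 < x0 || y1 < y0 || z1 < z0) return;
  const size_t bytes = (size_t)C * (x1 - x0 + 1) * sizeof(float);
  for (int z = z0; z <= z1; ++z) {
    for (int y = y0; y <= y1; ++y) {
      const int src = (x0 + dx) + d * ((y + dy) + h * (z + dz));
      const int dst = x0 + d * (y + h * z);
      std::memcpy(buf.colptr(dst), X.colptr(src), bytes);
    }
  }
}

// dX[., n + offset] += T[., n] over the valid region (adjoint of
// shifted_copy).
static void shifted_add(const FM& T, int d, int h, int w, int dx, int dy,
                        int dz, FM& dX) {
  const int C = T.n_rows;
  const int x0 = std::max(0, -dx), x1 = std::min(d, d - dx) - 1;
  const int y0 = std::max(0, -dy), y1 = std::min(h, h - dy) - 1;
  const int z0 = std::max(0, -dz), z1 = std::min(w, w - dz) - 1;
  if (x1 < x0 || y1 < y0 || z1 < z0) return;
  const size_t len = (size_t)C * (x1 - x0 + 1);
  for (int z = z0; z <= z1; ++z) {
    for (int y = y0; y <= y1; ++y) {
      const float* src = T.colptr(x0 + d * (y + h * z));
      float* dst = dX.colptr((x0 + dx) + d * ((y + dy) + h * (z + dz)));
      for (size_t i = 0; i < len; ++i) dst[i] += src[i];
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv3_fwd")]]
arma::mat cpp_conv3_fwd(const arma::mat& X, const arma::mat& W,
                        const arma::vec& b, int d, int h, int w) {
  FM Xf = to_f(X), Wf = to_f(W);
  FV bf = arma::conv_to<FV>::from(b);
  const int C = Xf.n_rows;
  const int N = d * h * w;
  FM Y(Wf.n_rows, N, arma::fill::zeros);
  FM buf(C, N);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        shifted_copy(Xf, d, h, w, dx, dy, dz, buf);
        Y += Wf.cols(k * C, k * C + C - 1) * buf;
      }
  Y.each_col() += bf;
  return to_d(Y);
}

// [[Rcpp::export(name = ".cpp_conv3_bwd")]]
List cpp_conv3_bwd(const arma::mat& X, const arma::mat& W,
                   const arma::mat& dY, int d, int h, int w) {
  FM Xf = to_f(X), Wf = to_f(W), dYf = to_f(dY);
  const int C = Xf.n_rows;
  const int N = d * h * w;
  FM dW(Wf.n_rows, Wf.n_cols, arma::fill::zeros);
  FM dX(C, N, arma::fill::zeros);
  FM buf(C, N), T;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        shifted_copy(Xf, d, h, w, dx, dy, dz, buf);
        dW.cols(k * C, k * C + C - 1) = dYf * buf.t();
        T = Wf.cols(k * C, k * C + C - 1).t() * dYf;
        shifted_add(T, d, h, w, dx, dy, dz, dX);
      }
  arma::fvec db = arma::sum(dYf, 1);
  return List::create(_["dW"] = to_d(dW),
                      _["db"] = arma::conv_to<arma::vec>::from(db),
                      _["dX"] = to_d(dX));
}

// 2x2x2 max pooling with stride 2; returns pooled map and 1-based argmax
// voxel indices (C x Nout) for the backward scatter.
// [[Rcpp::export(name = ".cpp_pool_fwd")]]
List cpp_pool_fwd(const arma::mat& X, int d, int h, int w) {
  const int C = X.n_rows;
  const int d2 = d / 2, h2 = h / 2, w2 = w / 2;
  const int Nout = d2 * h2 * w2;
  arma::mat Y(C, Nout);
  arma::imat idx(C, Nout);
  int n = 0;
  for (int z = 0; z < w2; ++z) {
    for (int y = 0; y < h2; ++y) {
      for (int x = 0; x < d2; ++x, ++n) {
        for (int c = 0; c < C; ++c) {
          double best = -1e30;
          int besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int m = (2 * x + dx) + d * ((2 * y + dy) + h * (2 * z + dz));
                const double v = X(c, m);
                if (v > best) { best = v; besti = m; }
              }
          Y(c, n) = best;
          idx(c, n) = besti + 1;
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_pool_bwd")]]
arma::mat cpp_pool_bwd(const arma::mat& dY, const arma::imat& idx, int N) {
  const int C = dY.n_rows;
  arma::mat dX(C, N, arma::fill::zeros);
  for (arma::uword n = 0; n < dY.n_cols; ++n)
    for (int c = 0; c < C; ++c)
      dX(c, idx(c, n) - 1) += dY(c, n);
  return dX;
}

// Transposed 2x2x2 convolution, stride 2. W is (C_out*8 x C_in); block
// row c*8..c*8+7 ordering not used directly -- rows are laid out as
// k*C_out + c with k = dx + 2*dy + 4*dz the sub-voxel offset.
// [[Rcpp::export(name = ".cpp_upconv_fwd")]]
arma::mat cpp_upconv_fwd(const arma::mat& X, const arma::mat& W,
                         const arma::vec& b, int d, int h, int w) {
  FM Xf = to_f(X), Wf = to_f(W);
  const int Cout = (int)W.n_rows / 8;
  FM B = Wf * Xf;  // (8*Cout) x Nlow
  const int d2 = 2 * d, h2 = 2 * h, w2 = 2 * w;
  FM Y(Cout, d2 * h2 * w2);
  int n = 0;
  for (int z = 0; z < w; ++z) {
    for (int y = 0; y < h; ++y) {
      for (int x = 0; x < d; ++x, ++n) {
        const float* bn = B.colptr(n);
        for (int k = 0; k < 8; ++k) {
          const int dx = k & 1, dy = (k >> 1) & 1, dz = (k >> 2) & 1;
          const int m = (2 * x + dx) + d2 * ((2 * y + dy) + h2 * (2 * z + dz));
          std::memcpy(Y.colptr(m), bn + k * Cout, Cout * sizeof(float));
        }
      }
    }
  }
  FV bf = arma::conv_to<FV>::from(b);
  Y.each_col() += bf;
  return to_d(Y);
}

// [[Rcpp::export(name = ".cpp_upconv_bwd")]]
List cpp_upconv_bwd(const arma::mat& X, const arma::mat& W,
                    const arma::mat& dY, int d, int h, int w) {
  FM Xf = to_f(X), Wf = to_f(W), dYf = to_f(dY);
  const int Cout = (int)dY.n_rows;
  const int d2 = 2 * d, h2 = 2 * h, w2 = 2 * w;
  FM dB(8 * Cout, d * h * w);
  int n = 0;
  for (int z = 0; z < w; ++z) {
    for (int y = 0; y < h; ++y) {
      for (int x = 0; x < d; ++x, ++n) {
        float* bn = dB.colptr(n);
        for (int k = 0; k < 8; ++k) {
          const int dx = k & 1, dy = (k >> 1) & 1, dz = (k >> 2) & 1;
          const int m = (2 * x + dx) + d2 * ((2 * y + dy) + h2 * (2 * z + dz));
          std::memcpy(bn + k * Cout, dYf.colptr(m), Cout * sizeof(float));
        }
      }
    }
  }
  FM dW = dB * Xf.t();
  FM dX = Wf.t() * dB;
  arma::fvec db = arma::sum(dYf, 1);
  return List::create(_["dW"] = to_d(dW),
                      _["db"] = arma::conv_to<arma::vec>::from(db),
                      _["dX"] = to_d(dX));
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sampling of src (dims ds) at arbitrary continuous 0-based
// coordinates (3 x N), clamped to the volume.
static void sample_trilinear(const arma::vec& src, const arma::ivec& ds,
                             const arma::mat& pos, arma::vec& out) {
  const int d = ds[0], h = ds[1], w = ds[2];
  out.set_size(pos.n_cols);
  for (arma::uword n = 0; n < pos.n_cols; ++n) {
    double px = clampd(pos(0, n), 0.0, d - 1.0);
    double py = clampd(pos(1, n), 0.0, h - 1.0);
    double pz = clampd(pos(2, n), 0.0, w - 1.0);
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    int x1 = std::min(x0 + 1, d - 1), y1 = std::min(y0 + 1, h - 1),
        z1 = std::min(z0 + 1, w - 1);
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    double v = 0.0;
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          const int xx = kx ? x1 : x0, yy = ky ? y1 : y0, zz = kz ? z1 : z0;
          const double wgt = (kx ? fx : 1 - fx) * (ky ? fy : 1 - fy) *
                             (kz ? fz : 1 - fz);
          v += wgt * src[xx + d * (yy + h * zz)];
        }
    out[n] = v;
  }
}

static void sample_nearest(const arma::vec& src, const arma::ivec& ds,
                           const arma::mat& pos, arma::vec& out) {
  const int d = ds[0], h = ds[1], w = ds[2];
  out.set_size(pos.n_cols);
  for (arma::uword n = 0; n < pos.n_cols; ++n) {
    int x = (int)clampd(std::round(pos(0, n)), 0.0, d - 1.0);
    int y = (int)clampd(std::round(pos(1, n)), 0.0, h - 1.0);
    int z = (int)clampd(std::round(pos(2, n)), 0.0, w - 1.0);
    out[n] = src[x + d * (y + h * z)];
  }
}

static arma::mat grid_positions(int td, int th, int tw, int sd, int sh, int sw) {
  arma::mat pos(3, (arma::uword)td * th * tw);
  const double rx = (double)sd / td, ry = (double)sh / th, rz = (double)sw / tw;
  arma::uword n = 0;
  for (int z = 0; z < tw; ++z)
    for (int y = 0; y < th; ++y)
      for (int x = 0; x < td; ++x, ++n) {
        pos(0, n) = (x + 0.5) * rx - 0.5;
        pos(1, n) = (y + 0.5) * ry - 0.5;
        pos(2, n) = (z + 0.5) * rz - 0.5;
      }
  return pos;
}

// [[Rcpp::export(name = ".cpp_resample")]]
arma::vec cpp_resample(const arma::vec& src, const arma::ivec& src_dims,
                       const arma::ivec& tgt_dims, bool nearest) {
  arma::mat pos = grid_positions(tgt_dims[0], tgt_dims[1], tgt_dims[2],
                                 src_dims[0], src_dims[1], src_dims[2]);
  arma::vec out;
  if (nearest) sample_nearest(src, src_dims, pos, out);
  else sample_trilinear(src, src_dims, pos, out);
  return out;
}

// Warp by a per-voxel displacement field (voxel units): value at voxel v is
// sampled from position v + disp(v).
// [[Rcpp::export(name = ".cpp_warp")]]
arma::vec cpp_warp(const arma::vec& src, const arma::ivec& dims,
                   const arma::vec& dx, const arma::vec& dy,
                   const arma::vec& dz, bool nearest) {
  const int d = dims[0], h = dims[1], w = dims[2];
  arma::mat pos(3, (arma::uword)d * h * w);
  arma::uword n = 0;
  for (int z = 0; z < w; ++z)
    for (int y = 0; y < h; ++y)
      for (int x = 0; x < d; ++x, ++n) {
        pos(0, n) = x + dx[n];
        pos(1, n) = y + dy[n];
        pos(2, n) = z + dz[n];
      }
  arma::vec out;
  if (nearest) sample_nearest(src, dims, pos, out);
  else sample_trilinear(src, dims, pos, out);
  return out;
}

// Separable Gaussian smoothing (truncated at 3 sigma, renormalised at the
// borders), used for phantom partial-volume blur and elastic-field smoothing.
// [[Rcpp::export(name = ".cpp_gauss_smooth")]]
arma::vec cpp_gauss_smooth(const arma::vec& src, const arma::ivec& dims,
                           double sigma) {
  const int d = dims[0], h = dims[1], w = dims[2];
  if (sigma <= 0) return src;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec ker(2 * r + 1);
  for (int i = -r; i <= r; ++i) ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  arma::vec cur = src, nxt(src.n_elem);
  const int strides[3] = {1, d, d * h};
  const int sizes[3] = {d, h, w};
  for (int ax = 0; ax < 3; ++ax) {
    const int st = strides[ax], sz = sizes[ax];
    for (int z = 0; z < w; ++z)
      for (int y = 0; y < h; ++y)
        for (int x = 0; x < d; ++x) {
          const int coord[3] = {x, y, z};
          const int n = x + d * (y + h * z);
          double acc = 0, wsum = 0;
          for (int i = -r; i <= r; ++i) {
            const int c = coord[ax] + i;
            if (c < 0 || c >= sz) continue;
            const double kv = ker[i + r];
            acc += kv * cur[n + i * st];
            wsum += kv;
          }
          nxt[n] = acc / wsum;
        }
    cur = nxt;
  }
  return cur;
}

// One Adam update. The moment buffers m and v are updated in place (they
// are owned exclusively by the optimizer environment); the updated
// parameter is returned as a fresh object so snapshots of the parameter
// list are never aliased.
// [[Rcpp::export(name = ".cpp_adam_update")]]
NumericVector cpp_adam_update(NumericVector p, NumericVector m,
                              NumericVector v, NumericVector g,
                              double lr, double beta1, double beta2,
                              double eps, double wd, double bc1, double bc2) {
  const R_xlen_t n = p.size();
  NumericVector out = clone(p);
  double* mp = REAL(m);
  double* vp = REAL(v);
  const double* gp = REAL(g);
  double* op = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
    double step = lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
    if (wd > 0) step += lr * wd * op[i];
    op[i] -= step;
  }
  return out;
}
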