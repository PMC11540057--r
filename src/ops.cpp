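#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Volumes are stored as R arrays with dim (D, H, W, C), column-major, so the
// x-index varies fastest.  im2col lays the receptive field of every output
// voxel out as one row; column order is kx-fastest then ky, kz, channel, which
// matches a weight array of dim (k, k, k, C_in, C_out) flattened to a
// (k^3*C_in) x C_out matrix.  Convolution is then a single GEMM done in R.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, const IntegerVector& dims,
                         int k, int stride, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = (D + 2 * pad - k) / stride + 1;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  const int K = k * k * k * C;
  NumericMatrix out(N, K);
  const double* px = x.begin();
  double* po = out.begin();
  const R_xlen_t planeDH = (R_xlen_t)D * H;
  const R_xlen_t volDHW = planeDH * W;
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * kz) + k * k * k * c;
          double* pcol = po + (R_xlen_t)col * N;
          const int off = kx - pad;           // stride-1 x offset
          // valid output-x range for the contiguous fast path
          const int x_lo = std::max(0, -off);
          const int x_hi = std::min(Do, D - off);
          R_xlen_t idx = 0;
          for (int wz = 0; wz < Wo; ++wz) {
            const int z = wz * stride - pad + kz;
            const bool zin = (z >= 0 && z < W);
            for (int hy = 0; hy < Ho; ++hy) {
              const int y = hy * stride - pad + ky;
              const bool yin = (y >= 0 && y < H);
              if (!zin || !yin) {
                std::fill(pcol + idx, pcol + idx + Do, 0.0);
                idx += Do;
                continue;
              }
              const double* base = px + (R_xlen_t)D * (y + (R_xlen_t)H * z) + volDHW * c;
              if (stride == 1) {
                if (x_lo > 0) std::fill(pcol + idx, pcol + idx + x_lo, 0.0);
                if (x_hi > x_lo)
                  std::copy(base + x_lo + off, base + x_hi + off, pcol + idx + x_lo);
                if (x_hi < Do) std::fill(pcol + idx + std::max(x_hi, x_lo), pcol + idx + Do, 0.0);
                idx += Do;
              } else {
                for (int dx = 0; dx < Do; ++dx) {
                  const int xx = dx * stride - pad + kx;
                  pcol[idx++] = (xx >= 0 && xx < D) ? base[xx] : 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add a (N x K) matrix of column gradients back to
// the input layout.  Used for the data gradient of conv3d.
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& cols, const IntegerVector& dims,
                         int k, int stride, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = (D + 2 * pad - k) / stride + 1;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  NumericVector out((R_xlen_t)D * H * W * C);
  double* px = out.begin();
  const double* po = cols.begin();
  const R_xlen_t planeDH = (R_xlen_t)D * H;
  const R_xlen_t volDHW = planeDH * W;
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * kz) + k * k * k * c;
          const double* pcol = po + (R_xlen_t)col * N;
          const int off = kx - pad;
          const int x_lo = std::max(0, -off);
          const int x_hi = std::min(Do, D - off);
          R_xlen_t idx = 0;
          for (int wz = 0; wz < Wo; ++wz) {
            const int z = wz * stride - pad + kz;
            const bool zin = (z >= 0 && z < W);
            for (int hy = 0; hy < Ho; ++hy) {
              const int y = hy * stride - pad + ky;
              if (!zin || y < 0 || y >= H) { idx += Do; continue; }
              double* base = px + (R_xlen_t)D * (y + (R_xlen_t)H * z) + volDHW * c;
              if (stride == 1) {
                for (int dx = x_lo; dx < x_hi; ++dx)
                  base[dx + off] += pcol[idx + dx];
                idx += Do;
              } else {
                for (int dx = 0; dx < Do; ++dx) {
                  const int xx = dx * stride - pad + kx;
                  if (xx >= 0 && xx < D) base[xx] += pcol[idx];
                  ++idx;
                }
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

static inline void axis_weights(int n_out, int n_in, std::vector<int>& i0,
                                std::vector<int>& i1, std::vector<double>& w1) {
  // scale factor 2, half-voxel alignment (align_corners = FALSE convention)
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(src);
    double w = src - lo;
    if (lo < 0) { lo = 0; w = 0.0; }
    int hi = lo + 1;
    if (hi > n_in - 1) { hi = n_in - 1; w = 0.0; }
    i0[o] = lo; i1[o] = hi; w1[o] = w;
  }
}

// Trilinear upsampling by a factor of 2 per axis, channel-wise.
// [[Rcpp::export]]
NumericVector cpp_upsample2(const NumericVector& x, const IntegerVector& dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  std::vector<int> xi0, xi1, yi0, yi1, zi0, zi1;
  std::vector<double> xw, yw, zw;
  axis_weights(Do, D, xi0, xi1, xw);
  axis_weights(Ho, H, yi0, yi1, yw);
  axis_weights(Wo, W, zi0, zi1, zw);
  NumericVector out((R_xlen_t)Do * Ho * Wo * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (R_xlen_t)D * H * W * c;
    double* oc = po + (R_xlen_t)Do * Ho * Wo * c;
    R_xlen_t idx = 0;
    for (int z = 0; z < Wo; ++z) {
      const double wz = zw[z];
      const R_xlen_t z0 = (R_xlen_t)zi0[z] * D * H, z1 = (R_xlen_t)zi1[z] * D * H;
      for (int y = 0; y < Ho; ++y) {
        const double wy = yw[y];
        const R_xlen_t y0 = (R_xlen_t)yi0[y] * D, y1 = (R_xlen_t)yi1[y] * D;
        for (int xo = 0; xo < Do; ++xo) {
          const double wx = xw[xo];
          const int x0 = xi0[xo], x1 = xi1[xo];
          const double v000 = xc[x0 + y0 + z0], v100 = xc[x1 + y0 + z0];
          const double v010 = xc[x0 + y1 + z0], v110 = xc[x1 + y1 + z0];
          const double v001 = xc[x0 + y0 + z1], v101 = xc[x1 + y0 + z1];
          const double v011 = xc[x0 + y1 + z1], v111 = xc[x1 + y1 + z1];
          const double c00 = v000 * (1 - wx) + v100 * wx;
          const double c10 = v010 * (1 - wx) + v110 * wx;
          const double c01 = v001 * (1 - wx) + v101 * wx;
          const double c11 = v011 * (1 - wx) + v111 * wx;
          const double c0 = c00 * (1 - wy) + c10 * wy;
          const double c1 = c01 * (1 - wy) + c11 * wy;
          oc[idx++] = c0 * (1 - wz) + c1 * wz;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return out;
}

// Adjoint of cpp_upsample2: scatter an upsampled-size gradient back down.
// [[Rcpp::export]]
NumericVector cpp_upsample2_adj(const NumericVector& g, const IntegerVector& dims_in) {
  const int D = dims_in[0], H = dims_in[1], W = dims_in[2], C = dims_in[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  std::vector<int> xi0, xi1, yi0, yi1, zi0, zi1;
  std::vector<double> xw, yw, zw;
  axis_weights(Do, D, xi0, xi1, xw);
  axis_weights(Ho, H, yi0, yi1, yw);
  axis_weights(Wo, W, zi0, zi1, zw);
  NumericVector out((R_xlen_t)D * H * W * C);
  const double* pg = g.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    double* oc = po + (R_xlen_t)D * H * W * c;
    const double* gc = pg + (R_xlen_t)Do * Ho * Wo * c;
    R_xlen_t idx = 0;
    for (int z = 0; z < Wo; ++z) {
      const double wz = zw[z];
      const R_xlen_t z0 = (R_xlen_t)zi0[z] * D * H, z1 = (R_xlen_t)zi1[z] * D * H;
      for (int y = 0; y < Ho; ++y) {
        const double wy = yw[y];
        const R_xlen_t y0 = (R_xlen_t)yi0[y] * D, y1 = (R_xlen_t)yi1[y] * D;
        for (int xo = 0; xo < Do; ++xo) {
          const double gv = gc[idx++];
          if (gv == 0.0) continue;
          const double wx = xw[xo];
          const int x0 = xi0[xo], x1 = xi1[xo];
          oc[x0 + y0 + z0] += gv * (1 - wx) * (1 - wy) * (1 - wz);
          oc[x1 + y0 + z0] += gv * wx * (1 - wy) * (1 - wz);
          oc[x0 + y1 + z0] += gv * (1 - wx) * wy * (1 - wz);
          oc[x1 + y1 + z0] += gv * wx * wy * (1 - wz);
          oc[x0 + y0 + z1] += gv * (1 - wx) * (1 - wy) * wz;
          oc[x1 + y0 + z1] += gv * wx * (1 - wy) * wz;
          oc[x0 + y1 + z1] += gv * (1 - wx) * wy * wz;
          oc[x1 + y1 + z1] += gv * wx * wy * wz;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(D, H, W, C);
  return out;
}

// --- exact Euclidean distance transform (squared), separable lower envelope
// of parabolas per axis; supports anisotropic voxel spacing.

static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zbuf) {
  const int n = (int)f.size();
  if (n == 1) { d[0] = f[0]; return; }
  const double INF = 1e60;
  int kk = 0;
  v[0] = 0;
  zbuf[0] = -INF;
  zbuf[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] >= INF && f[v[kk]] >= INF) { continue; }
    double sep;
    while (true) {
      const double xq = q * s, xv = v[kk] * s;
      sep = ((f[q] + xq * xq) - (f[v[kk]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sep <= zbuf[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    zbuf[kk] = sep;
    zbuf[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (zbuf[kk + 1] < xq) ++kk;
    const double dx = xq - v[kk] * s;
    d[q] = dx * dx + f[v[kk]];
  }
}

// Distance (in physical units) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(const LogicalVector& mask, const IntegerVector& dims,
                      const NumericVector& spacing) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const double INF = 1e60;
  std::vector<double> dist((R_xlen_t)D * H * W);
  for (R_xlen_t i = 0; i < (R_xlen_t)D * H * W; ++i)
    dist[i] = mask[i] ? 0.0 : INF;
  const int nmax = std::max(D, std::max(H, W));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // x axis
  for (int z = 0; z < W; ++z)
    for (int y = 0; y < H; ++y) {
      double* row = &dist[(R_xlen_t)D * (y + (R_xlen_t)H * z)];
      f.assign(row, row + D);
      f.resize(D); d.resize(D);
      dt1d(f, spacing[0], d, v, zbuf);
      std::copy(d.begin(), d.begin() + D, row);
    }
  // y axis
  for (int z = 0; z < W; ++z)
    for (int x = 0; x < D; ++x) {
      f.resize(H); d.resize(H);
      for (int y = 0; y < H; ++y) f[y] = dist[x + (R_xlen_t)D * (y + (R_xlen_t)H * z)];
      dt1d(f, spacing[1], d, v, zbuf);
      for (int y = 0; y < H; ++y) dist[x + (R_xlen_t)D * (y + (R_xlen_t)H * z)] = d[y];
    }
  // z axis
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < D; ++x) {
      f.resize(W); d.resize(W);
      for (int z = 0; z < W; ++z) f[z] = dist[x + (R_xlen_t)D * (y + (R_xlen_t)H * z)];
      dt1d(f, spacing[2], d, v, zbuf);
      for (int z = 0; z < W; ++z) dist[x + (R_xlen_t)D * (y + (R_xlen_t)H * z)] = d[z];
    }
  NumericVector out((R_xlen_t)D * H * W);
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = dist[i] >= INF ? R_PosInf : std::sqrt(dist[i]);
  out.attr("dim") = IntegerVector::create(D, H, W);
  return out;
}
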