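// Local shape descriptors: per-voxel Gaussian-weighted statistics (offset to
// local center of mass, coordinate variances and correlations, local size) of
// the object containing each voxel.  Computed per label by separable
// convolution with the truncated Gaussian over the label's padded bounding
// box; exactly equivalent to per-voxel summation over the 3-sigma box.
//
// Arrays follow the (z, y, x) convention with linear index z + nz*(y + ny*x).
// Output is channel-first (C, z, y, x) with channels ordered: mean offsets,
// variances, pairwise correlations, size.  C = 10 in 3D (axes z,y,x), 6 in 2D
// (per-section statistics over y,x only).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>

using namespace Rcpp;

static inline double clip01(double v) { return v < 0 ? 0.0 : (v > 1 ? 1.0 : v); }

// in-place separable convolution along one axis of a box-shaped field
static void conv_axis(std::vector<double> &f, std::vector<double> &tmp,
                      int bz, int by, int bx, int axis,
                      const std::vector<double> &ker, int K) {
  if (K == 0) return; // delta kernel
  int n_ax[3] = {bz, by, bx};
  R_xlen_t s[3] = {1, (R_xlen_t)bz, (R_xlen_t)bz * by};
  int n = n_ax[axis];
  R_xlen_t st = s[axis];
  tmp.assign(f.size(), 0.0);
  for (int z = 0; z < (axis == 0 ? 1 : bz); ++z)
    for (int y = 0; y < (axis == 1 ? 1 : by); ++y)
      for (int x = 0; x < (axis == 2 ? 1 : bx); ++x) {
        R_xlen_t base = (axis == 0 ? 0 : z) + (R_xlen_t)bz * ((axis == 1 ? 0 : y) + (R_xlen_t)by * (axis == 2 ? 0 : x));
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          int lo = std::max(0, i - K), hi = std::min(n - 1, i + K);
          for (int j = lo; j <= hi; ++j) acc += ker[j - i + K] * f[base + st * j];
          tmp[base + st * i] = acc;
        }
      }
  std::swap(f, tmp);
}

// [[Rcpp::export]]
NumericVector cpp_compute_lsd(NumericVector labels, NumericVector voxel_size,
                              NumericVector sigma, bool two_d) {
  IntegerVector dim = labels.attr("dim");
  if (dim.size() != 3) stop("labels must be a 3D array");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double vs[3] = {voxel_size[0], voxel_size[1], voxel_size[2]};
  double sg[3] = {sigma[0], sigma[1], sigma[2]};
  int K[3];
  std::vector<double> ker[3];
  double Ssum[3];
  for (int a = 0; a < 3; ++a) {
    if (two_d && a == 0) { K[a] = 0; ker[a] = {1.0}; Ssum[a] = 1.0; continue; }
    if (sg[a] <= 0) stop("sigma must be positive");
    K[a] = (int)std::floor(3.0 * sg[a] / vs[a] + 1e-9);
    ker[a].resize(2 * K[a] + 1);
    Ssum[a] = 0.0;
    for (int d = -K[a]; d <= K[a]; ++d) {
      double w = std::exp(-0.5 * (d * vs[a]) * (d * vs[a]) / (sg[a] * sg[a]));
      ker[a][d + K[a]] = w;
      Ssum[a] += w;
    }
  }
  double m_iso = Ssum[1] * Ssum[2] * (two_d ? 1.0 : Ssum[0]);
  int C = two_d ? 6 : 10;

  NumericVector out((R_xlen_t)C * nz * ny * nx);
  out.attr("dim") = IntegerVector::create(C, nz, ny, nx);

  // bounding boxes per label
  std::map<double, std::array<int, 6>> bbox; // zlo zhi ylo yhi xlo xhi
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double L = labels[(R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
        if (L == 0) continue;
        auto it = bbox.find(L);
        if (it == bbox.end()) bbox[L] = {z, z, y, y, x, x};
        else {
          auto &b = it->second;
          b[0] = std::min(b[0], z); b[1] = std::max(b[1], z);
          b[2] = std::min(b[2], y); b[3] = std::max(b[3], y);
          b[4] = std::min(b[4], x); b[5] = std::max(b[5], x);
        }
      }

  // field layout: 0 m, 1..3 first moments (z,y,x), 4..9 second moments
  // (zz, yy, xx, zy, zx, yx); 2D skips the z-containing ones
  const int NM = 10;
  std::vector<double> F[NM], tmp;

  for (auto &kv : bbox) {
    double L = kv.first;
    auto &b = kv.second;
    int zlo = std::max(0, b[0] - K[0]), zhi = std::min(nz - 1, b[1] + K[0]);
    int ylo = std::max(0, b[2] - K[1]), yhi = std::min(ny - 1, b[3] + K[1]);
    int xlo = std::max(0, b[4] - K[2]), xhi = std::min(nx - 1, b[5] + K[2]);
    int bz = zhi - zlo + 1, by = yhi - ylo + 1, bx = xhi - xlo + 1;
    R_xlen_t bn = (R_xlen_t)bz * by * bx;
    // world coordinates centered at the box corner (numerical conditioning)
    bool use[NM];
    for (int f = 0; f < NM; ++f)
      use[f] = !(two_d && (f == 1 || f == 4 || f == 7 || f == 8));
    for (int f = 0; f < NM; ++f) if (use[f]) F[f].assign(bn, 0.0);
    for (int x = xlo; x <= xhi; ++x)
      for (int y = ylo; y <= yhi; ++y)
        for (int z = zlo; z <= zhi; ++z) {
          if (labels[(R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] != L) continue;
          R_xlen_t bi = (R_xlen_t)(z - zlo) + (R_xlen_t)bz * ((y - ylo) + (R_xlen_t)by * (x - xlo));
          double wz = (z - zlo) * vs[0], wy = (y - ylo) * vs[1], wx = (x - xlo) * vs[2];
          F[0][bi] = 1.0;
          if (!two_d) { F[1][bi] = wz; F[4][bi] = wz * wz; F[7][bi] = wz * wy; F[8][bi] = wz * wx; }
          F[2][bi] = wy; F[3][bi] = wx;
          F[5][bi] = wy * wy; F[6][bi] = wx * wx; F[9][bi] = wy * wx;
        }
    for (int f = 0; f < NM; ++f) {
      if (!use[f]) continue;
      for (int a = 0; a < 3; ++a) conv_axis(F[f], tmp, bz, by, bx, a, ker[a], K[a]);
    }
    // fill output at voxels of this label
    for (int x = b[4]; x <= b[5]; ++x)
      for (int y = b[2]; y <= b[3]; ++y)
        for (int z = b[0]; z <= b[1]; ++z) {
          R_xlen_t vi = (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
          if (labels[vi] != L) continue;
          R_xlen_t bi = (R_xlen_t)(z - zlo) + (R_xlen_t)bz * ((y - ylo) + (R_xlen_t)by * (x - xlo));
          double m = F[0][bi];
          if (m <= 0) continue;
          double mean[3] = {0, 0, 0}, var[3] = {0, 0, 0}, cov[3] = {0, 0, 0};
          double wv[3] = {(z - zlo) * vs[0], (y - ylo) * vs[1], (x - xlo) * vs[2]};
          if (!two_d) mean[0] = F[1][bi] / m;
          mean[1] = F[2][bi] / m;
          mean[2] = F[3][bi] / m;
          if (!two_d) var[0] = F[4][bi] / m - mean[0] * mean[0];
          var[1] = F[5][bi] / m - mean[1] * mean[1];
          var[2] = F[6][bi] / m - mean[2] * mean[2];
          if (!two_d) {
            cov[0] = F[7][bi] / m - mean[0] * mean[1]; // (z,y)
            cov[1] = F[8][bi] / m - mean[0] * mean[2]; // (z,x)
          }
          cov[2] = F[9][bi] / m - mean[1] * mean[2];   // (y,x)
          for (int a = 0; a < 3; ++a) if (var[a] < 0) var[a] = 0;
          R_xlen_t o = (R_xlen_t)C * vi;
          if (!two_d) {
            double mu[3], corr[3];
            for (int a = 0; a < 3; ++a) mu[a] = mean[a] - wv[a];
            const int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};
            for (int c = 0; c < 3; ++c) {
              double den = var[pa[c]] * var[pb[c]];
              corr[c] = den > 1e-24 ? cov[c] / std::sqrt(den) : 0.0;
            }
            for (int a = 0; a < 3; ++a) out[o + a] = clip01(mu[a] / (2.0 * sg[a]) + 0.5);
            for (int a = 0; a < 3; ++a) out[o + 3 + a] = clip01(var[a] / (sg[a] * sg[a]));
            for (int c = 0; c < 3; ++c) out[o + 6 + c] = clip01((corr[c] + 1.0) / 2.0);
            out[o + 9] = clip01(m / m_iso);
          } else {
            double muy = mean[1] - wv[1], mux = mean[2] - wv[2];
            double den = var[1] * var[2];
            double corr = den > 1e-24 ? cov[2] / std::sqrt(den) : 0.0;
            out[o + 0] = clip01(muy / (2.0 * sg[1]) + 0.5);
            out[o + 1] = clip01(mux / (2.0 * sg[2]) + 0.5);
            out[o + 2] = clip01(var[1] / (sg[1] * sg[1]));
            out[o + 3] = clip01(var[2] / (sg[2] * sg[2]));
            out[o + 4] = clip01((corr + 1.0) / 2.0);
            out[o + 5] = clip01(m / m_iso);
          }
        }
  }
  return out;
}
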