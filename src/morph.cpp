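// Low-level grid morphology: separable Gaussian smoothing, anisotropic
// Euclidean distance transform, seeded watershed on a face-constrained voxel
// graph, connected-component labelling, local maxima, and 3D homotopic
// thinning.  All arrays use the package's (z, y, x) convention: R arrays with
// dim = c(nz, ny, nx), so linear index = z + nz * (y + ny * x).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static inline R_xlen_t lidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// strides along z, y, x for the linear index above
static inline void strides(int nz, int ny, R_xlen_t s[3]) {
  s[0] = 1; s[1] = nz; s[2] = (R_xlen_t)nz * ny;
}

static void get_dims(const RObject &x, int d[3]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  d[0] = dim[0]; d[1] = dim[1]; d[2] = dim[2];
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector x, NumericVector sigma_vox,
                                double truncate = 3.0) {
  int d[3]; get_dims(x, d);
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t s[3]; strides(nz, ny, s);
  int n_ax[3] = {nz, ny, nx};
  std::vector<double> cur(x.begin(), x.end()), nxt(cur.size());
  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigma_vox[ax];
    if (sg <= 0) continue;
    int K = (int)std::floor(truncate * sg + 1e-9);
    std::vector<double> ker(2 * K + 1);
    double tot = 0.0;
    for (int k = -K; k <= K; ++k) { ker[k + K] = std::exp(-0.5 * k * k / (sg * sg)); tot += ker[k + K]; }
    for (auto &v : ker) v /= tot;
    int n = n_ax[ax];
    R_xlen_t st = s[ax];
    // iterate over all lines along axis ax
    for (int z = 0; z < (ax == 0 ? 1 : nz); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y)
        for (int xx = 0; xx < (ax == 2 ? 1 : nx); ++xx) {
          R_xlen_t base = lidx(ax == 0 ? 0 : z, ax == 1 ? 0 : y, ax == 2 ? 0 : xx, nz, ny);
          for (int i = 0; i < n; ++i) {
            double acc = 0.0, wsum = 0.0;
            int lo = std::max(0, i - K), hi = std::min(n - 1, i + K);
            for (int j = lo; j <= hi; ++j) {
              double w = ker[j - i + K];
              acc += w * cur[base + st * j];
              wsum += w;
            }
            nxt[base + st * i] = acc / wsum; // renormalized at borders
          }
        }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = x.attr("dim");
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with spacing w
static void dt1d(std::vector<double> &f, std::vector<double> &dout,
                 std::vector<int> &v, std::vector<double> &zb, int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    while (true) {
      if (f[v[k]] == INF) { // previous parabola at infinity: replace
        k--;
        if (k < 0) { k = 0; v[0] = q; zb[0] = -INF; zb[1] = INF; goto placed; }
        continue;
      }
      {
        double ss = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
                    (2.0 * w2 * q - 2.0 * w2 * v[k]);
        if (ss <= zb[k]) { k--; if (k < 0) { k = 0; v[0] = q; zb[0] = -INF; zb[1] = INF; goto placed; } continue; }
        k++; v[k] = q; zb[k] = ss; zb[k + 1] = INF;
        goto placed;
      }
    }
    placed:;
  }
  if (f[v[0]] == INF) { // whole line infinite
    for (int q = 0; q < n; ++q) dout[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) k++;
    double dq = w * (q - v[k]);
    dout[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (world units) from each true voxel to the nearest false
// voxel; false voxels get 0; all-true input gives Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, NumericVector voxel_size) {
  int d[3]; get_dims(mask, d);
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t s[3]; strides(nz, ny, s);
  int n_ax[3] = {nz, ny, nx};
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), dout(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  for (int ax = 0; ax < 3; ++ax) {
    int n = n_ax[ax];
    R_xlen_t st = s[ax];
    double w = voxel_size[ax];
    for (int z = 0; z < (ax == 0 ? 1 : nz); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y)
        for (int xx = 0; xx < (ax == 2 ? 1 : nx); ++xx) {
          R_xlen_t base = lidx(ax == 0 ? 0 : z, ax == 1 ? 0 : y, ax == 2 ? 0 : xx, nz, ny);
          bool any_fin = false;
          for (int i = 0; i < n; ++i) { f[i] = g[base + st * i]; if (f[i] != INF) any_fin = true; }
          if (!any_fin) continue;
          dt1d(f, dout, v, zb, n, w);
          for (int i = 0; i < n; ++i) g[base + st * i] = dout[i];
        }
  }
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = mask.attr("dim");
  return out;
}

struct QEntry {
  double pri;
  uint64_t counter;
  R_xlen_t idx;
  int lab;
};
struct QCmp {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.pri != b.pri) return a.pri > b.pri; // min-heap on priority
    return a.counter > b.counter;             // FIFO on ties
  }
};

// Seeded watershed by priority flooding on the voxel graph whose vertices are
// `allow`-true voxels and whose edges are faces with face_ok true.  face_ok is
// a (3, nz, ny, nx) logical array; channel d at voxel p refers to the face
// between p and p + offset_d, offsets = (-1,0,0), (0,-1,0), (0,0,-1).
// Flooding proceeds in increasing `priority` order from the nonzero entries of
// `seeds`; neighbor order and a FIFO tie-break make the result deterministic.
// With accumulate = true the flood instead grows regions by accumulated
// traversal cost (Dijkstra on cost = priority[j] * step_cost[axis], seeds at
// cost 0), i.e. a geodesic watershed in the noise-cost metric.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, LogicalVector allow,
                            IntegerVector seeds, LogicalVector face_ok,
                            bool accumulate = false,
                            Nullable<NumericVector> step_cost = R_NilValue) {
  NumericVector sc(3, 1.0);
  if (step_cost.isNotNull()) sc = NumericVector(step_cost);
  int d[3]; get_dims(priority, d);
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t nvox = priority.size();
  IntegerVector lab(nvox, 0);
  lab.attr("dim") = priority.attr("dim");
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  uint64_t counter = 0;
  // face_ok linear index: d + 3*(z + nz*(y + ny*x))
  auto face = [&](int dch, R_xlen_t vox) -> bool {
    return face_ok[(R_xlen_t)dch + 3 * vox];
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lidx(z, y, x, nz, ny);
        if (seeds[i] > 0 && allow[i]) {
          lab[i] = seeds[i];
          pq.push({accumulate ? 0.0 : priority[i], counter++, i, seeds[i]});
        }
      }
  const int doff[3][3] = {{-1,0,0},{0,-1,0},{0,0,-1}};
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int z = (int)(e.idx % nz);
    int y = (int)((e.idx / nz) % ny);
    int x = (int)(e.idx / ((R_xlen_t)nz * ny));
    for (int dch = 0; dch < 3; ++dch) {
      for (int sgn = 0; sgn < 2; ++sgn) {
        int zz = z + (sgn ? -doff[dch][0] : doff[dch][0]);
        int yy = y + (sgn ? -doff[dch][1] : doff[dch][1]);
        int xx = x + (sgn ? -doff[dch][2] : doff[dch][2]);
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = lidx(zz, yy, xx, nz, ny);
        if (!allow[j] || lab[j] != 0) continue;
        // the face channel lives at the voxel with the larger coordinate
        R_xlen_t fvox = sgn ? j : e.idx;
        if (!face(dch, fvox)) continue;
        lab[j] = lab[e.idx];
        double pj = accumulate
          ? e.pri + std::max(priority[j], 0.0) * sc[dch]
          : priority[j];
        pq.push({pj, counter++, j, lab[j]});
      }
    }
  }
  return lab;
}

// Connected components of equal nonzero labels; connectivity 6 or 26.
// Optional face_ok (3,nz,ny,nx) restricts 6-connectivity to allowed faces
// (pass a zero-length vector to disable).
// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector labels, int connectivity,
                                   LogicalVector face_ok) {
  int d[3]; get_dims(labels, d);
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t nvox = labels.size();
  bool use_face = face_ok.size() > 0;
  IntegerVector comp(nvox, 0);
  comp.attr("dim") = labels.attr("dim");
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int doff[3][3] = {{-1,0,0},{0,-1,0},{0,0,-1}};
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        R_xlen_t i0 = lidx(z0, y0, x0, nz, ny);
        if (labels[i0] == 0 || comp[i0] != 0) continue;
        double val = labels[i0];
        ++next;
        comp[i0] = next;
        stack.push_back(i0);
        while (!stack.empty()) {
          R_xlen_t i = stack.back(); stack.pop_back();
          int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / ((R_xlen_t)nz * ny));
          if (connectivity == 6) {
            for (int dch = 0; dch < 3; ++dch)
              for (int sgn = 0; sgn < 2; ++sgn) {
                int zz = z + (sgn ? -doff[dch][0] : doff[dch][0]);
                int yy = y + (sgn ? -doff[dch][1] : doff[dch][1]);
                int xx = x + (sgn ? -doff[dch][2] : doff[dch][2]);
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
                R_xlen_t j = lidx(zz, yy, xx, nz, ny);
                if (comp[j] != 0 || labels[j] != val) continue;
                if (use_face) {
                  R_xlen_t fvox = sgn ? j : i;
                  if (!face_ok[(R_xlen_t)dch + 3 * fvox]) continue;
                }
                comp[j] = next;
                stack.push_back(j);
              }
          } else {
            for (int dz = -1; dz <= 1; ++dz)
              for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                  if (!dz && !dy && !dx) continue;
                  int zz = z + dz, yy = y + dy, xx = x + dx;
                  if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
                  R_xlen_t j = lidx(zz, yy, xx, nz, ny);
                  if (comp[j] == 0 && labels[j] == val) { comp[j] = next; stack.push_back(j); }
                }
          }
        }
      }
  return comp;
}

// Local maxima of `value` within `domain` under a box footprint of half-widths
// radii (z,y,x): true where value >= every domain value in the box.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector value, LogicalVector domain,
                               IntegerVector radii) {
  int d[3]; get_dims(value, d);
  int nz = d[0], ny = d[1], nx = d[2];
  LogicalVector out(value.size(), FALSE);
  out.attr("dim") = value.attr("dim");
  int rz = radii[0], ry = radii[1], rx = radii[2];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lidx(z, y, x, nz, ny);
        if (!domain[i]) continue;
        double v = value[i];
        bool ismax = true;
        for (int dz = -rz; dz <= rz && ismax; ++dz)
          for (int dy = -ry; dy <= ry && ismax; ++dy)
            for (int dx = -rx; dx <= rx && ismax; ++dx) {
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              R_xlen_t j = lidx(zz, yy, xx, nz, ny);
              if (domain[j] && value[j] > v) ismax = false;
            }
        out[i] = ismax;
      }
  return out;
}

// ---- 3D homotopic thinning -------------------------------------------------

// component counting inside the 3x3x3 neighborhood
static int count_components_26(const bool nb[27]) {
  // nb indexed (dz+1) + 3*((dy+1) + 3*(dx+1)); center excluded by caller
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ncomp++;
    int stack[27], sp = 0;
    stack[sp++] = s; seen[s] = true;
    while (sp) {
      int c = stack[--sp];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int zz = cz + dz, yy = cy + dy, xx = cx + dx;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
            int j = zz + 3 * (yy + 3 * xx);
            if (j == 13 || j == c || !nb[j] || seen[j]) continue;
            seen[j] = true; stack[sp++] = j;
          }
    }
  }
  return ncomp;
}

// 6-connected components of background within the 18-neighborhood that are
// 6-adjacent to the center
static int count_bg_components_6_18(const bool nb[27]) {
  bool in18[27], bg[27], seen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    int cz = s % 3 - 1, cy = (s / 3) % 3 - 1, cx = s / 9 - 1;
    int man = std::abs(cz) + std::abs(cy) + std::abs(cx);
    in18[s] = (man == 1 || man == 2);
    bg[s] = in18[s] && !nb[s];
  }
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!bg[s] || seen[s]) continue;
    // flood this component; record whether it touches the center 6-adjacently
    bool touches = false;
    int stack[27], sp = 0;
    stack[sp++] = s; seen[s] = true;
    while (sp) {
      int c = stack[--sp];
      int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
      if (std::abs(cz) + std::abs(cy) + std::abs(cx) == 1) touches = true;
      const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int zz = cz + step[k][0] + 1, yy = cy + step[k][1] + 1, xx = cx + step[k][2] + 1;
        if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
        int j = zz + 3 * (yy + 3 * xx);
        if (!bg[j] || seen[j]) continue;
        seen[j] = true; stack[sp++] = j;
      }
    }
    if (touches) ncomp++;
  }
  return ncomp;
}

// Distance-ordered homotopic thinning to a curve skeleton: repeatedly delete
// simple, non-endpoint voxels in increasing distance order (26-connected
// foreground, 6-connected background).
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, NumericVector dist) {
  int d[3]; get_dims(mask, d);
  int nz = d[0], ny = d[1], nx = d[2];
  std::vector<char> obj(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) obj[i] = mask[i] ? 1 : 0;

  auto neighborhood = [&](int z, int y, int x, bool nb[27]) {
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int s = (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
          int zz = z + dz, yy = y + dy, xx = x + dx;
          bool v = false;
          if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
            v = obj[lidx(zz, yy, xx, nz, ny)] != 0;
          nb[s] = v;
          if (v && s != 13) cnt++;
        }
    return cnt;
  };

  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  uint64_t counter = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lidx(z, y, x, nz, ny);
        if (obj[i]) pq.push({dist[i], counter++, i, 0});
      }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    R_xlen_t i = e.idx;
    if (!obj[i]) continue;
    int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / ((R_xlen_t)nz * ny));
    bool nb[27];
    int nnb = neighborhood(z, y, x, nb);
    if (nnb <= 1) continue; // endpoint (or isolated): keep
    nb[13] = false;
    if (count_components_26(nb) != 1) continue;
    if (count_bg_components_6_18(nb) != 1) continue;
    obj[i] = 0; // simple: delete, re-queue neighbors
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          R_xlen_t j = lidx(zz, yy, xx, nz, ny);
          if (obj[j]) pq.push({dist[j], counter++, j, 0});
        }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = obj[i] != 0;
  out.attr("dim") = mask.attr("dim");
  return out;
}

// Binary erosion (op = 0) or dilation (op = 1) with an explicit structuring
// element given as a k x 3 matrix of (dz, dy, dx) offsets; voxels outside the
// volume count as background.
// [[Rcpp::export]]
LogicalVector cpp_morph_binary(LogicalVector mask, IntegerMatrix offsets, int op) {
  int d[3]; get_dims(mask, d);
  int nz = d[0], ny = d[1], nx = d[2];
  LogicalVector out(mask.size());
  out.attr("dim") = mask.attr("dim");
  int k = offsets.nrow();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lidx(z, y, x, nz, ny);
        bool acc = (op == 0);
        for (int t = 0; t < k; ++t) {
          int zz = z + offsets(t, 0), yy = y + offsets(t, 1), xx = x + offsets(t, 2);
          bool v = false;
          if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
            v = mask[lidx(zz, yy, xx, nz, ny)];
          if (op == 0) { if (!v) { acc = false; break; } }
          else { if (v) { acc = true; break; } }
        }
        out[i] = acc;
      }
  return out;
}
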