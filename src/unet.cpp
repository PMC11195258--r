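// A compact U-Net with explicit forward and backward passes.  Tensors are
// channel-first (c, z, y, x) matching R arrays with dim = c(C, nz, ny, nx)
// (channel index fastest).  Convolutions use odd kernels with zero
// same-padding; downsampling is max-pooling, upsampling nearest-neighbor,
// skip connections are channel concatenation; hidden activations ReLU, head
// outputs sigmoid.  The training step returns the masked weighted MSE loss
// (summed over heads) and exact parameter gradients.
//
// Architecture description (R list `spec`):
//   in_channels  int
//   features     integer vector, one entry per resolution level (L+1)
//   factors      integer matrix L x 3, pooling factors (z,y,x) per level
//   kernel       integer vector (kz, ky, kx), odd
//   heads        integer vector of output channel counts (named)
//
// Parameter list order: encoder blocks 0..L (two convs each: W, b, W, b),
// then decoder blocks L-1..0 (two convs each), then one 1x1x1 conv per head.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Ten {
  int c = 0, z = 0, y = 0, x = 0;
  std::vector<double> v;
  void init(int c_, int z_, int y_, int x_) {
    c = c_; z = z_; y = y_; x = x_;
    v.assign((size_t)c * z * y * x, 0.0);
  }
  inline size_t sp(int zz, int yy, int xx) const {
    return (size_t)zz + (size_t)z * ((size_t)yy + (size_t)y * xx);
  }
};

struct ConvShape { int co, ci, kz, ky, kx; };

// kernel-offset-outer convolution: per offset, a branch-free sweep over the
// valid cuboid with contiguous channel blocks
static void conv_fwd(const Ten &in, const double *W, const double *b,
                     const ConvShape &cs, Ten &out) {
  out.init(cs.co, in.z, in.y, in.x);
  int rz = cs.kz / 2, ry = cs.ky / 2, rx = cs.kx / 2;
  // initialize with bias
  size_t nsp = (size_t)in.z * in.y * in.x;
  for (size_t s = 0; s < nsp; ++s)
    for (int oc = 0; oc < cs.co; ++oc) out.v[s * cs.co + oc] = b[oc];
  for (int dx = -rx; dx <= rx; ++dx)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dz = -rz; dz <= rz; ++dz) {
        size_t k3 = (size_t)(dz + rz) + (size_t)cs.kz * ((size_t)(dy + ry) + (size_t)cs.ky * (dx + rx));
        const double *Wk = W + (size_t)cs.co * cs.ci * k3;
        int z0 = std::max(0, -dz), z1 = in.z - 1 - std::max(0, dz);
        int y0 = std::max(0, -dy), y1 = in.y - 1 - std::max(0, dy);
        int x0 = std::max(0, -dx), x1 = in.x - 1 - std::max(0, dx);
        for (int x = x0; x <= x1; ++x)
          for (int y = y0; y <= y1; ++y) {
            size_t p = out.sp(z0, y, x);
            size_t q = in.sp(z0 + dz, y + dy, x + dx);
            for (int z = z0; z <= z1; ++z, ++p, ++q) {
              const double *iv = &in.v[q * cs.ci];
              double *ov = &out.v[p * cs.co];
              for (int ic = 0; ic < cs.ci; ++ic) {
                double v = iv[ic];
                const double *Wc = Wk + (size_t)cs.co * ic;
                for (int oc = 0; oc < cs.co; ++oc) ov[oc] += Wc[oc] * v;
              }
            }
          }
      }
}

static void conv_bwd(const Ten &in, const double *W, const ConvShape &cs,
                     const Ten &gout, Ten &gin, double *gW, double *gb) {
  gin.init(in.c, in.z, in.y, in.x);
  int rz = cs.kz / 2, ry = cs.ky / 2, rx = cs.kx / 2;
  size_t nsp = (size_t)in.z * in.y * in.x;
  for (size_t s = 0; s < nsp; ++s)
    for (int oc = 0; oc < cs.co; ++oc) gb[oc] += gout.v[s * cs.co + oc];
  for (int dx = -rx; dx <= rx; ++dx)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dz = -rz; dz <= rz; ++dz) {
        size_t k3 = (size_t)(dz + rz) + (size_t)cs.kz * ((size_t)(dy + ry) + (size_t)cs.ky * (dx + rx));
        double *Wk = gW + (size_t)cs.co * cs.ci * k3;
        const double *Wf = W + (size_t)cs.co * cs.ci * k3;
        int z0 = std::max(0, -dz), z1 = in.z - 1 - std::max(0, dz);
        int y0 = std::max(0, -dy), y1 = in.y - 1 - std::max(0, dy);
        int x0 = std::max(0, -dx), x1 = in.x - 1 - std::max(0, dx);
        for (int x = x0; x <= x1; ++x)
          for (int y = y0; y <= y1; ++y) {
            size_t p = gout.sp(z0, y, x);
            size_t q = in.sp(z0 + dz, y + dy, x + dx);
            for (int z = z0; z <= z1; ++z, ++p, ++q) {
              const double *iv = &in.v[q * cs.ci];
              const double *go = &gout.v[p * cs.co];
              double *gi = &gin.v[q * cs.ci];
              for (int ic = 0; ic < cs.ci; ++ic) {
                double v = iv[ic];
                double acc = 0.0;
                double *Wc = Wk + (size_t)cs.co * ic;
                const double *Wfc = Wf + (size_t)cs.co * ic;
                for (int oc = 0; oc < cs.co; ++oc) {
                  Wc[oc] += go[oc] * v;
                  acc += Wfc[oc] * go[oc];
                }
                gi[ic] += acc;
              }
            }
          }
      }
}

static void relu_fwd(Ten &t) {
  for (auto &v : t.v) if (v < 0) v = 0;
}
static void relu_bwd(const Ten &out, Ten &g) {
  for (size_t i = 0; i < g.v.size(); ++i) if (out.v[i] <= 0) g.v[i] = 0;
}

static void pool_fwd(const Ten &in, int fz, int fy, int fx, Ten &out,
                     std::vector<size_t> &argmax) {
  out.init(in.c, in.z / fz, in.y / fy, in.x / fx);
  argmax.assign(out.v.size(), 0);
  for (int x = 0; x < out.x; ++x)
    for (int y = 0; y < out.y; ++y)
      for (int z = 0; z < out.z; ++z)
        for (int c = 0; c < in.c; ++c) {
          double best = -1e300; size_t bi = 0;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                size_t q = in.sp(z * fz + dz, y * fy + dy, x * fx + dx) * in.c + c;
                if (in.v[q] > best) { best = in.v[q]; bi = q; }
              }
          size_t p = out.sp(z, y, x) * out.c + c;
          out.v[p] = best; argmax[p] = bi;
        }
}
static void pool_bwd(const Ten &in, const Ten &gout,
                     const std::vector<size_t> &argmax, Ten &gin) {
  gin.init(in.c, in.z, in.y, in.x);
  for (size_t p = 0; p < gout.v.size(); ++p) gin.v[argmax[p]] += gout.v[p];
}

static void up_fwd(const Ten &in, int fz, int fy, int fx, Ten &out) {
  out.init(in.c, in.z * fz, in.y * fy, in.x * fx);
  for (int x = 0; x < out.x; ++x)
    for (int y = 0; y < out.y; ++y)
      for (int z = 0; z < out.z; ++z) {
        size_t p = out.sp(z, y, x) * out.c;
        size_t q = in.sp(z / fz, y / fy, x / fx) * in.c;
        for (int c = 0; c < in.c; ++c) out.v[p + c] = in.v[q + c];
      }
}
static void up_bwd(const Ten &in, const Ten &gout, int fz, int fy, int fx, Ten &gin) {
  gin.init(in.c, in.z, in.y, in.x);
  for (int x = 0; x < gout.x; ++x)
    for (int y = 0; y < gout.y; ++y)
      for (int z = 0; z < gout.z; ++z) {
        size_t p = gout.sp(z, y, x) * gout.c;
        size_t q = gin.sp(z / fz, y / fy, x / fx) * gin.c;
        for (int c = 0; c < gout.c; ++c) gin.v[q + c] += gout.v[p + c];
      }
}

static void concat_fwd(const Ten &a, const Ten &b, Ten &out) {
  out.init(a.c + b.c, a.z, a.y, a.x);
  size_t nsp = (size_t)a.z * a.y * a.x;
  for (size_t s = 0; s < nsp; ++s) {
    for (int c = 0; c < a.c; ++c) out.v[s * out.c + c] = a.v[s * a.c + c];
    for (int c = 0; c < b.c; ++c) out.v[s * out.c + a.c + c] = b.v[s * b.c + c];
  }
}
static void concat_bwd(const Ten &gout, int ca, int cb, Ten &ga, Ten &gb,
                       int z, int y, int x) {
  ga.init(ca, z, y, x); gb.init(cb, z, y, x);
  size_t nsp = (size_t)z * y * x;
  for (size_t s = 0; s < nsp; ++s) {
    for (int c = 0; c < ca; ++c) ga.v[s * ca + c] = gout.v[s * gout.c + c];
    for (int c = 0; c < cb; ++c) gb.v[s * cb + c] = gout.v[s * gout.c + ca + c];
  }
}

struct Arch {
  int in_channels, L;
  std::vector<int> features;
  std::vector<std::array<int, 3>> factors;
  int kz, ky, kx;
  std::vector<int> heads;
};

static Arch parse_arch(const List &spec) {
  Arch a;
  a.in_channels = as<int>(spec["in_channels"]);
  a.features = as<std::vector<int>>(spec["features"]);
  a.L = (int)a.features.size() - 1;
  IntegerMatrix fm = spec["factors"];
  for (int l = 0; l < a.L; ++l) a.factors.push_back({fm(l, 0), fm(l, 1), fm(l, 2)});
  IntegerVector k = spec["kernel"];
  a.kz = k[0]; a.ky = k[1]; a.kx = k[2];
  a.heads = as<std::vector<int>>(spec["heads"]);
  return a;
}

struct PIdx { ConvShape cs; int w, b; }; // indices into the parameter list

static std::vector<PIdx> param_layout(const Arch &a) {
  std::vector<PIdx> ly;
  int i = 0;
  for (int l = 0; l <= a.L; ++l) {
    int ci = l == 0 ? a.in_channels : a.features[l - 1];
    int f = a.features[l];
    ly.push_back({{f, ci, a.kz, a.ky, a.kx}, i, i + 1}); i += 2;
    ly.push_back({{f, f, a.kz, a.ky, a.kx}, i, i + 1}); i += 2;
  }
  for (int l = a.L - 1; l >= 0; --l) {
    int f = a.features[l];
    ly.push_back({{f, f + a.features[l + 1], a.kz, a.ky, a.kx}, i, i + 1}); i += 2;
    ly.push_back({{f, f, a.kz, a.ky, a.kx}, i, i + 1}); i += 2;
  }
  for (size_t h = 0; h < a.heads.size(); ++h) {
    ly.push_back({{a.heads[h], a.features[0], 1, 1, 1}, i, i + 1}); i += 2;
  }
  return ly;
}

struct FwdState {
  std::vector<Ten> enc_a, enc_b, pooled;   // per level
  std::vector<std::vector<size_t>> argmax; // per pooling
  std::vector<Ten> ups, cats, dec_a, dec_b; // decoder, stored bottom-up order
  std::vector<Ten> head_pre, head_out;
};

static void forward(const Arch &a, const std::vector<PIdx> &ly, const List &params,
                    const Ten &input, FwdState &st) {
  std::vector<const double *> P(params.size());
  for (int i = 0; i < params.size(); ++i) P[i] = REAL(params[i]);
  int li = 0;
  st.enc_a.resize(a.L + 1); st.enc_b.resize(a.L + 1);
  st.pooled.resize(a.L); st.argmax.resize(a.L);
  const Ten *cur = &input;
  for (int l = 0; l <= a.L; ++l) {
    conv_fwd(*cur, P[ly[li].w], P[ly[li].b], ly[li].cs, st.enc_a[l]); relu_fwd(st.enc_a[l]); li++;
    conv_fwd(st.enc_a[l], P[ly[li].w], P[ly[li].b], ly[li].cs, st.enc_b[l]); relu_fwd(st.enc_b[l]); li++;
    if (l < a.L) {
      pool_fwd(st.enc_b[l], a.factors[l][0], a.factors[l][1], a.factors[l][2],
               st.pooled[l], st.argmax[l]);
      cur = &st.pooled[l];
    }
  }
  st.ups.resize(a.L); st.cats.resize(a.L); st.dec_a.resize(a.L); st.dec_b.resize(a.L);
  const Ten *deep = &st.enc_b[a.L];
  for (int l = a.L - 1; l >= 0; --l) {
    up_fwd(*deep, a.factors[l][0], a.factors[l][1], a.factors[l][2], st.ups[l]);
    concat_fwd(st.enc_b[l], st.ups[l], st.cats[l]);
    conv_fwd(st.cats[l], P[ly[li].w], P[ly[li].b], ly[li].cs, st.dec_a[l]); relu_fwd(st.dec_a[l]); li++;
    conv_fwd(st.dec_a[l], P[ly[li].w], P[ly[li].b], ly[li].cs, st.dec_b[l]); relu_fwd(st.dec_b[l]); li++;
    deep = &st.dec_b[l];
  }
  const Ten &feat = a.L == 0 ? st.enc_b[0] : st.dec_b[0];
  st.head_pre.resize(a.heads.size()); st.head_out.resize(a.heads.size());
  for (size_t h = 0; h < a.heads.size(); ++h) {
    conv_fwd(feat, P[ly[li].w], P[ly[li].b], ly[li].cs, st.head_pre[h]); li++;
    st.head_out[h] = st.head_pre[h];
    for (auto &v : st.head_out[h].v) v = 1.0 / (1.0 + std::exp(-v));
  }
}

static NumericVector ten_to_r(const Ten &t) {
  NumericVector out(t.v.begin(), t.v.end());
  out.attr("dim") = IntegerVector::create(t.c, t.z, t.y, t.x);
  return out;
}
static Ten r_to_ten(const NumericVector &x) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a (c, z, y, x) array");
  Ten t; t.c = dim[0]; t.z = dim[1]; t.y = dim[2]; t.x = dim[3];
  t.v.assign(x.begin(), x.end());
  return t;
}

// [[Rcpp::export]]
List cpp_unet_forward(List spec, List params, NumericVector input) {
  Arch a = parse_arch(spec);
  auto ly = param_layout(a);
  Ten in = r_to_ten(input);
  FwdState st;
  forward(a, ly, params, in, st);
  List out(a.heads.size());
  for (size_t h = 0; h < a.heads.size(); ++h) out[h] = ten_to_r(st.head_out[h]);
  out.names() = as<CharacterVector>(spec["head_names"]);
  return out;
}

// [[Rcpp::export]]
List cpp_unet_train_step(List spec, List params, NumericVector input,
                         List targets, List weights) {
  Arch a = parse_arch(spec);
  auto ly = param_layout(a);
  Ten in = r_to_ten(input);
  FwdState st;
  forward(a, ly, params, in, st);

  // loss and head gradients
  double loss = 0.0;
  std::vector<Ten> ghead(a.heads.size());
  for (size_t h = 0; h < a.heads.size(); ++h) {
    Ten tg = r_to_ten(targets[h]);
    Ten wt = r_to_ten(weights[h]);
    const Ten &pr = st.head_out[h];
    double wsum = 0.0, num = 0.0;
    for (size_t i = 0; i < pr.v.size(); ++i) {
      double d = pr.v[i] - tg.v[i];
      num += wt.v[i] * d * d;
      wsum += wt.v[i];
    }
    double den = std::max(wsum, 1e-8);
    loss += num / den;
    ghead[h].init(pr.c, pr.z, pr.y, pr.x);
    for (size_t i = 0; i < pr.v.size(); ++i) {
      double gp = 2.0 * wt.v[i] * (pr.v[i] - tg.v[i]) / den;
      // through sigmoid
      ghead[h].v[i] = gp * pr.v[i] * (1.0 - pr.v[i]);
    }
  }

  // gradient buffers
  List grads(params.size());
  std::vector<double *> G(params.size());
  for (int i = 0; i < params.size(); ++i) {
    NumericVector p = params[i];
    NumericVector g(p.size());
    if (!Rf_isNull(p.attr("dim"))) g.attr("dim") = p.attr("dim");
    grads[i] = g;
    G[i] = REAL(g);
  }
  std::vector<const double *> P(params.size());
  for (int i = 0; i < params.size(); ++i) P[i] = REAL(params[i]);

  // backward through heads
  int li = (int)ly.size() - 1;
  const Ten &feat = a.L == 0 ? st.enc_b[0] : st.dec_b[0];
  Ten gfeat; gfeat.init(feat.c, feat.z, feat.y, feat.x);
  for (int h = (int)a.heads.size() - 1; h >= 0; --h, --li) {
    Ten gf;
    conv_bwd(feat, P[ly[li].w], ly[li].cs, ghead[h], gf, G[ly[li].w], G[ly[li].b]);
    for (size_t i = 0; i < gfeat.v.size(); ++i) gfeat.v[i] += gf.v[i];
  }

  // backward through decoder
  Ten gdeep = gfeat;
  for (int l = 0; l < a.L; ++l) {
    Ten g = gdeep, gin;
    relu_bwd(st.dec_b[l], g);
    conv_bwd(st.dec_a[l], P[ly[li].w], ly[li].cs, g, gin, G[ly[li].w], G[ly[li].b]); --li;
    relu_bwd(st.dec_a[l], gin);
    Ten gcat;
    conv_bwd(st.cats[l], P[ly[li].w], ly[li].cs, gin, gcat, G[ly[li].w], G[ly[li].b]); --li;
    Ten gskip, gup;
    concat_bwd(gcat, st.enc_b[l].c, st.ups[l].c, gskip, gup,
               st.cats[l].z, st.cats[l].y, st.cats[l].x);
    // upsample backward into the deeper feature
    const Ten &deeper = (l == a.L - 1) ? st.enc_b[a.L] : st.dec_b[l + 1];
    Ten gdeeper;
    up_bwd(deeper, gup, a.factors[l][0], a.factors[l][1], a.factors[l][2], gdeeper);
    gdeep = gdeeper;
    // stash skip gradient for the encoder pass
    st.ups[l] = gskip; // reuse storage: ups[l] now holds the skip gradient
  }

  // backward through encoder (deepest first)
  Ten gnext = gdeep; // gradient on enc_b[L]
  for (int l = a.L; l >= 0; --l) {
    Ten g = gnext;
    if (l < a.L) {
      // combine pooled-path gradient with the stored skip gradient
      Ten gpool;
      pool_bwd(st.enc_b[l], g, st.argmax[l], gpool);
      g = gpool;
      for (size_t i = 0; i < g.v.size(); ++i) g.v[i] += st.ups[l].v[i];
    }
    relu_bwd(st.enc_b[l], g);
    // li currently points at encoder conv b of level l
    Ten gin;
    conv_bwd(st.enc_a[l], P[ly[li].w], ly[li].cs, g, gin, G[ly[li].w], G[ly[li].b]); --li;
    relu_bwd(st.enc_a[l], gin);
    const Ten &blockin = (l == 0) ? in : st.pooled[l - 1];
    Ten gblockin;
    conv_bwd(blockin, P[ly[li].w], ly[li].cs, gin, gblockin, G[ly[li].w], G[ly[li].b]); --li;
    gnext = gblockin; // gradient on pooled[l-1]
  }

  List preds(a.heads.size());
  for (size_t h = 0; h < a.heads.size(); ++h) preds[h] = ten_to_r(st.head_out[h]);
  preds.names() = as<CharacterVector>(spec["head_names"]);
  return List::create(_["loss"] = loss, _["grads"] = grads, _["preds"] = preds);
}
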