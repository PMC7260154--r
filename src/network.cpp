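// Numerical core: 2-D convolution (im2col + GEMM), max pooling, the
// convolutional GRU cell, and a fused forward/backward pass over a whole
// frame sequence (backpropagation through time) for training.
//
// Conventions shared with the R side (see param_spec() in R/network.R):
//  * a frame is an H x W matrix; feature maps are H x W x C cubes
//    (column-major within a slice, slices consecutive — identical to how R
//    stores an H x W x C array);
//  * a conv kernel bank is stored as a C_out x (C_in*k*k) matrix whose
//    column index is c_in*k*k + ky*k + kx (0-based; ky = row offset);
//  * all parameters of a model live in one flat numeric vector `theta`,
//    walked in a fixed canonical order: conv layers (W, b), C-GRU
//    (W_hr, W_xr, W_hz, W_xz, W_h, W_x, b_r, b_z, b), FC layers (W, b).
//
// Convolutions are cross-correlations (deep-learning convention); the C-GRU
// uses 3x3 kernels, stride 1, zero "same" padding so the state shape is
// preserved.
//
// Performance note: the unfolded patch matrix is kept TRANSPOSED,
// cols(ho*wo, cin*k*k), so that (a) unfolding writes memory contiguously
// and (b) an ho x wo x c cube and the GEMM operand/result (ho*wo) x c
// matrix are the same memory, making every cube<->matrix conversion a free
// reinterpretation (see mview/cview).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvSpec {
  int cin, cout, k, s, p;   // channels in/out, kernel, stride, zero-pad
  int hin, win, ho, wo;     // spatial dims before conv and after conv
  int pool;                 // square pool size applied after ReLU (0 = none)
  int hp, wp;               // spatial dims after pooling
};

struct NetCfg {
  int H, W, D, fh, fw;
  std::vector<ConvSpec> conv;
  std::vector<int> fc;      // fc[0] = D*fh*fw, ..., fc.back() = 1
};

int conv_out(int n, int k, int s, int p) { return (n + 2 * p - k) / s + 1; }

NetCfg parse_cfg(const Rcpp::List& cfg) {
  NetCfg c;
  c.H = Rcpp::as<int>(cfg["in_h"]);
  c.W = Rcpp::as<int>(cfg["in_w"]);
  Rcpp::IntegerVector co = cfg["conv_out"], ck = cfg["conv_k"],
                      cs = cfg["conv_s"], cp = cfg["conv_p"],
                      cl = cfg["conv_pool"];
  int h = c.H, w = c.W, cin = 1;
  for (int i = 0; i < co.size(); ++i) {
    ConvSpec s;
    s.cin = cin; s.cout = co[i]; s.k = ck[i]; s.s = cs[i]; s.p = cp[i];
    s.hin = h; s.win = w;
    s.ho = conv_out(h, s.k, s.s, s.p);
    s.wo = conv_out(w, s.k, s.s, s.p);
    if (s.ho < 1 || s.wo < 1) Rcpp::stop("conv layer %d collapses spatial dims", i + 1);
    s.pool = cl[i];
    if (s.pool > 1) {
      if (s.ho % s.pool || s.wo % s.pool)
        Rcpp::stop("pool size %d does not divide conv output %dx%d", s.pool, s.ho, s.wo);
      s.hp = s.ho / s.pool; s.wp = s.wo / s.pool;
    } else { s.hp = s.ho; s.wp = s.wo; }
    h = s.hp; w = s.wp; cin = s.cout;
    c.conv.push_back(s);
  }
  c.D = cin; c.fh = h; c.fw = w;
  Rcpp::IntegerVector fc = cfg["fc"];
  for (int i = 0; i < fc.size(); ++i) c.fc.push_back(fc[i]);
  if (c.fc.front() != c.D * c.fh * c.fw)
    Rcpp::stop("fc input width %d != flattened state %d", c.fc.front(), c.D * c.fh * c.fw);
  return c;
}

// zero-copy views between an ho x wo x c cube and its (ho*wo) x c matrix
inline mat mview(cube& x) {
  return mat(x.memptr(), x.n_rows * x.n_cols, x.n_slices, false, true);
}
inline mat cmview(const cube& x) { // read-only use; arma lacks const views
  return mat(const_cast<double*>(x.memptr()),
             x.n_rows * x.n_cols, x.n_slices, false, true);
}

// ---- im2col / col2im (transposed layout) ----------------------------------

// cols: (ho*wo) x (cin*k*k); row index oy + ox*ho, column c*k*k + ky*k + kx
void im2col(const cube& x, int k, int stride, int pad, int ho, int wo, mat& cols) {
  const int cin = x.n_slices, H = x.n_rows, W = x.n_cols;
  cols.set_size(ho * wo, cin * k * k);
  for (int c = 0; c < cin; ++c) {
    const mat& xc = x.slice(c);
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky) {
        double* dst = cols.colptr(c * k * k + ky * k + kx);
        for (int ox = 0; ox < wo; ++ox) {
          const int ix = ox * stride + kx - pad;
          double* d = dst + (uword)ox * ho;
          if (ix < 0 || ix >= W) {
            std::fill(d, d + ho, 0.0);
            continue;
          }
          const double* src = xc.colptr(ix);
          for (int oy = 0; oy < ho; ++oy) {
            const int iy = oy * stride + ky - pad;
            d[oy] = (iy >= 0 && iy < H) ? src[iy] : 0.0;
          }
        }
      }
  }
}

void col2im_add(const mat& gcols, int k, int stride, int pad, int ho, int wo, cube& gx) {
  const int cin = gx.n_slices, H = gx.n_rows, W = gx.n_cols;
  for (int c = 0; c < cin; ++c) {
    mat& gc = gx.slice(c);
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky) {
        const double* src = gcols.colptr(c * k * k + ky * k + kx);
        for (int ox = 0; ox < wo; ++ox) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= W) continue;
          double* dc = gc.colptr(ix);
          const double* s = src + (uword)ox * ho;
          for (int oy = 0; oy < ho; ++oy) {
            const int iy = oy * stride + ky - pad;
            if (iy >= 0 && iy < H) dc[iy] += s[oy];
          }
        }
      }
  }
}

// out = conv(x); cols (if given) receives the unfolded patches; Wt is the
// kkC x cout transposed kernel bank
cube conv_fw(const cube& x, const mat& Wt, const vec& b, int k, int s, int p,
             int ho, int wo, mat* cols_cache = nullptr) {
  mat local;
  mat& cols = cols_cache ? *cols_cache : local;
  im2col(x, k, s, p, ho, wo, cols);
  cube out(ho, wo, Wt.n_cols);
  mat ov = mview(out);
  ov = cols * Wt;
  ov.each_row() += b.t();
  return out;
}

// max pool, non-overlapping p x p; argmax linear index (within slice) cached
cube pool_fw(const cube& x, int p, umat* arg = nullptr) {
  const int ho = x.n_rows / p, wo = x.n_cols / p, C = x.n_slices;
  cube out(ho, wo, C);
  if (arg) arg->set_size(ho * wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int ox = 0; ox < wo; ++ox)
      for (int oy = 0; oy < ho; ++oy) {
        double best = -datum::inf; uword bi = 0;
        for (int dx = 0; dx < p; ++dx)
          for (int dy = 0; dy < p; ++dy) {
            const uword iy = oy * p + dy, ix = ox * p + dx;
            const double v = xc(iy, ix);
            if (v > best) { best = v; bi = ix * x.n_rows + iy; }
          }
        out(oy, ox, c) = best;
        if (arg) (*arg)(ox * ho + oy, c) = bi;
      }
  }
  return out;
}

void pool_bw_add(const cube& gout, const umat& arg, int p, cube& gx) {
  const int ho = gout.n_rows, wo = gout.n_cols, C = gout.n_slices;
  for (int c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    const mat& go = gout.slice(c);
    for (int ox = 0; ox < wo; ++ox)
      for (int oy = 0; oy < ho; ++oy)
        gc(arg(ox * ho + oy, c)) += go(oy, ox);
  }
}

// ---- parameter walking ----------------------------------------------------

struct ParamCursor {
  const double* base; uword off, len;
  ParamCursor(const double* b, uword n) : base(b), off(0), len(n) {}
  mat take_mat(uword r, uword c) {
    if (off + r * c > len) Rcpp::stop("theta too short");
    mat m(base + off, r, c); // owned copy
    off += r * c; return m;
  }
  vec take_vec(uword n) {
    if (off + n > len) Rcpp::stop("theta too short");
    vec v(base + off, n);
    off += n; return v;
  }
};

// kernel banks are stored transposed (kkC x cout) for the GEMMs; biases and
// FC weights keep their canonical orientation
struct Params {
  std::vector<mat> convWt; std::vector<vec> convB;
  mat Whr, Wxr, Whz, Wxz, Wh, Wx; vec br, bz, b;  // each kkD x D
  std::vector<mat> fcW; std::vector<vec> fcB;
};

Params walk_params(const double* base, uword n, const NetCfg& c) {
  ParamCursor cur(base, n);
  Params P;
  for (auto& s : c.conv) {
    P.convWt.push_back(cur.take_mat(s.cout, s.cin * s.k * s.k).t());
    P.convB.push_back(cur.take_vec(s.cout));
  }
  const uword D = c.D, kk = D * 9;
  P.Whr = cur.take_mat(D, kk).t(); P.Wxr = cur.take_mat(D, kk).t();
  P.Whz = cur.take_mat(D, kk).t(); P.Wxz = cur.take_mat(D, kk).t();
  P.Wh  = cur.take_mat(D, kk).t(); P.Wx  = cur.take_mat(D, kk).t();
  P.br = cur.take_vec(D); P.bz = cur.take_vec(D); P.b = cur.take_vec(D);
  for (size_t i = 1; i < c.fc.size(); ++i) {
    P.fcW.push_back(cur.take_mat(c.fc[i], c.fc[i - 1]));
    P.fcB.push_back(cur.take_vec(c.fc[i]));
  }
  if (cur.off != cur.len)
    Rcpp::stop("theta length %d does not match config (%d needed)", (int)cur.len, (int)cur.off);
  return P;
}

Params zero_like(const Params& P) {
  Params G;
  for (auto& m : P.convWt) G.convWt.push_back(mat(size(m), fill::zeros));
  for (auto& v : P.convB) G.convB.push_back(vec(size(v), fill::zeros));
  G.Whr = mat(size(P.Whr), fill::zeros); G.Wxr = mat(size(P.Wxr), fill::zeros);
  G.Whz = mat(size(P.Whz), fill::zeros); G.Wxz = mat(size(P.Wxz), fill::zeros);
  G.Wh  = mat(size(P.Wh),  fill::zeros); G.Wx  = mat(size(P.Wx),  fill::zeros);
  G.br = vec(size(P.br), fill::zeros); G.bz = vec(size(P.bz), fill::zeros);
  G.b  = vec(size(P.b),  fill::zeros);
  for (auto& m : P.fcW) G.fcW.push_back(mat(size(m), fill::zeros));
  for (auto& v : P.fcB) G.fcB.push_back(vec(size(v), fill::zeros));
  return G;
}

// serialize gradients back to the canonical (untransposed) flat order
vec flatten_params(const Params& P, uword n) {
  vec out(n);
  uword off = 0;
  auto put_mt = [&](const mat& m) { // stored transposed; emit original layout
    mat t = m.t();
    std::copy(t.begin(), t.end(), out.begin() + off); off += t.n_elem;
  };
  auto put_m = [&](const mat& m) { std::copy(m.begin(), m.end(), out.begin() + off); off += m.n_elem; };
  auto put_v = [&](const vec& v) { std::copy(v.begin(), v.end(), out.begin() + off); off += v.n_elem; };
  for (size_t i = 0; i < P.convWt.size(); ++i) { put_mt(P.convWt[i]); put_v(P.convB[i]); }
  put_mt(P.Whr); put_mt(P.Wxr); put_mt(P.Whz); put_mt(P.Wxz); put_mt(P.Wh); put_mt(P.Wx);
  put_v(P.br); put_v(P.bz); put_v(P.b);
  for (size_t i = 0; i < P.fcW.size(); ++i) { put_m(P.fcW[i]); put_v(P.fcB[i]); }
  if (off != n) Rcpp::stop("internal: flatten length mismatch");
  return out;
}

// ---- encoder / cgru / head forward with caches ----------------------------

struct ConvCache { mat cols; cube relu; umat poolarg; cube pooled; };
struct CgruCache {
  mat cols_x, cols_h, cols_rh;
  cube r, z, cand, h_prev, h;
};
struct FcCache { std::vector<vec> act; }; // act[0] input, act[i] layer i output

cube encoder_fw(const mat& frame, const Params& P, const NetCfg& c,
                std::vector<ConvCache>* cc) {
  cube x(frame.n_rows, frame.n_cols, 1);
  x.slice(0) = frame;
  for (size_t i = 0; i < c.conv.size(); ++i) {
    const ConvSpec& s = c.conv[i];
    ConvCache dummy;
    ConvCache& C = cc ? (*cc)[i] : dummy;
    cube o = conv_fw(x, P.convWt[i], P.convB[i], s.k, s.s, s.p, s.ho, s.wo, &C.cols);
    o.transform([](double v) { return v > 0.0 ? v : 0.0; });
    C.relu = o;
    if (s.pool > 1) {
      C.pooled = pool_fw(o, s.pool, &C.poolarg);
      x = C.pooled;
    } else x = o;
  }
  return x;
}

// accumulates conv-parameter grads into G; input grad is not needed
void encoder_bw(const cube& gtop, const Params& P, Params& G, const NetCfg& c,
                std::vector<ConvCache>& cc) {
  cube g = gtop;
  for (int i = (int)c.conv.size() - 1; i >= 0; --i) {
    const ConvSpec& s = c.conv[i];
    ConvCache& C = cc[i];
    if (s.pool > 1) {
      cube gr(s.ho, s.wo, s.cout, fill::zeros);
      pool_bw_add(g, C.poolarg, s.pool, gr);
      g = gr;
    }
    // ReLU mask
    for (uword j = 0; j < g.n_elem; ++j) if (C.relu(j) <= 0.0) g(j) = 0.0;
    mat gY = cmview(g);                         // (ho*wo) x cout, zero copy
    G.convWt[i] += C.cols.t() * gY;
    G.convB[i] += sum(gY, 0).t();
    if (i > 0) {
      mat gcols = gY * P.convWt[i].t();         // (ho*wo) x kkC
      cube gx(s.hin, s.win, s.cin, fill::zeros);
      col2im_add(gcols, s.k, s.s, s.p, s.ho, s.wo, gx);
      g = gx;
    }
  }
}

cube cgru_fw(const cube& x, const cube& h_prev, const Params& P, const NetCfg& c,
             CgruCache* cc) {
  const int fh = c.fh, fw = c.fw, D = c.D;
  CgruCache dummy;
  CgruCache& C = cc ? *cc : dummy;
  im2col(x, 3, 1, 1, fh, fw, C.cols_x);
  im2col(h_prev, 3, 1, 1, fh, fw, C.cols_h);
  C.r.set_size(fh, fw, D); C.z.set_size(fh, fw, D); C.cand.set_size(fh, fw, D);
  { mat rv = mview(C.r);
    rv = C.cols_h * P.Whr + C.cols_x * P.Wxr; rv.each_row() += P.br.t();
    rv.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); }); }
  { mat zv = mview(C.z);
    zv = C.cols_h * P.Whz + C.cols_x * P.Wxz; zv.each_row() += P.bz.t();
    zv.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); }); }
  cube rh = C.r % h_prev;
  im2col(rh, 3, 1, 1, fh, fw, C.cols_rh);
  { mat cv = mview(C.cand);
    cv = C.cols_rh * P.Wh + C.cols_x * P.Wx; cv.each_row() += P.b.t();
    cv.transform([](double v) { return std::tanh(v); }); }
  C.h_prev = h_prev;
  C.h = (1.0 - C.z) % h_prev + C.z % C.cand;
  return C.h;
}

// gh: grad wrt h[t]; returns grad wrt h_prev; accumulates param grads and gx
cube cgru_bw(const cube& gh, const Params& P, Params& G, const NetCfg& c,
             CgruCache& C, cube& gx) {
  const int fh = c.fh, fw = c.fw;
  cube gz = gh % (C.cand - C.h_prev);
  cube gcand = gh % C.z;
  cube gh_prev = gh % (1.0 - C.z);
  cube gcpre = gcand % (1.0 - square(C.cand));
  mat gc = cmview(gcpre);                       // (fh*fw) x D
  G.Wh += C.cols_rh.t() * gc;
  G.Wx += C.cols_x.t() * gc;
  G.b += sum(gc, 0).t();
  // back through cand convs
  cube grh(fh, fw, (uword)c.D, fill::zeros);
  col2im_add(gc * P.Wh.t(), 3, 1, 1, fh, fw, grh);
  col2im_add(gc * P.Wx.t(), 3, 1, 1, fh, fw, gx);
  cube gr = grh % C.h_prev;
  gh_prev += grh % C.r;
  cube grpre = gr % C.r % (1.0 - C.r);
  cube gzpre = gz % C.z % (1.0 - C.z);
  mat gr_m = cmview(grpre), gz_m = cmview(gzpre);
  G.Whr += C.cols_h.t() * gr_m; G.Wxr += C.cols_x.t() * gr_m; G.br += sum(gr_m, 0).t();
  G.Whz += C.cols_h.t() * gz_m; G.Wxz += C.cols_x.t() * gz_m; G.bz += sum(gz_m, 0).t();
  col2im_add(gr_m * P.Whr.t() + gz_m * P.Whz.t(), 3, 1, 1, fh, fw, gh_prev);
  col2im_add(gr_m * P.Wxr.t() + gz_m * P.Wxz.t(), 3, 1, 1, fh, fw, gx);
  return gh_prev;
}

double head_fw(const cube& h, const Params& P, const NetCfg& c, FcCache* cc) {
  vec a(const_cast<double*>(h.memptr()), h.n_elem); // flatten = same memory
  FcCache dummy;
  FcCache& C = cc ? *cc : dummy;
  C.act.clear(); C.act.push_back(a);
  for (size_t i = 0; i < P.fcW.size(); ++i) {
    a = P.fcW[i] * a + P.fcB[i];
    if (i + 1 < P.fcW.size()) a.transform([](double v) { return v > 0.0 ? v : 0.0; });
    C.act.push_back(a);
  }
  return a(0);
}

cube head_bw(double gy, const Params& P, Params& G, const NetCfg& c, FcCache& C) {
  vec g(1); g(0) = gy;
  for (int i = (int)P.fcW.size() - 1; i >= 0; --i) {
    if ((size_t)i + 1 < P.fcW.size()) // ReLU mask on this layer's output
      for (uword j = 0; j < g.n_elem; ++j) if (C.act[i + 1](j) <= 0.0) g(j) = 0.0;
    G.fcW[i] += g * C.act[i].t();
    G.fcB[i] += g;
    g = P.fcW[i].t() * g;
  }
  return cube(g.memptr(), c.fh, c.fw, c.D); // copy into state shape
}

// CyclicLoss pair list per the printed double sum: n = 0..Ncycles-1,
// t = 0..Tperiod inclusive; keep only pairs with both 0-based indices < K.
void cl_pairs(int K, int Tper, int Ncyc, std::vector<std::pair<int,int>>& out) {
  out.clear();
  if (Tper < 1 || Ncyc < 1) return;
  for (int n = 0; n < Ncyc; ++n)
    for (int t = 0; t <= Tper; ++t) {
      const int a = t + n * Tper, b = t + (n + 1) * Tper;
      if (a >= 0 && b >= 0 && b < K && a < K) out.push_back({a, b});
    }
}

} // namespace

// ---------------------------------------------------------------------------
// exported granular operations (user API + oracles)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                      int k, int stride, int pad) {
  if ((uword)(x.n_slices * k * k) != W.n_cols)
    Rcpp::stop("weight matrix columns (%d) != cin*k*k (%d)", (int)W.n_cols,
               (int)(x.n_slices * k * k));
  if (W.n_rows != b.n_elem) Rcpp::stop("bias length != output channels");
  const int ho = conv_out(x.n_rows, k, stride, pad);
  const int wo = conv_out(x.n_cols, k, stride, pad);
  if (ho < 1 || wo < 1) Rcpp::stop("convolution output would be empty");
  return conv_fw(x, W.t(), b, k, stride, pad, ho, wo);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool(const arma::cube& x, int p) {
  if (x.n_rows % p || x.n_cols % p) Rcpp::stop("pool size must divide input dims");
  return pool_fw(x, p);
}

// [[Rcpp::export]]
Rcpp::List cpp_cgru_step(const arma::cube& x, const arma::cube& h,
                         const arma::mat& Whr, const arma::mat& Wxr,
                         const arma::mat& Whz, const arma::mat& Wxz,
                         const arma::mat& Wh, const arma::mat& Wx,
                         const arma::vec& br, const arma::vec& bz,
                         const arma::vec& b) {
  if (x.n_rows != h.n_rows || x.n_cols != h.n_cols || x.n_slices != h.n_slices)
    Rcpp::stop("x and h shapes differ");
  const int D = x.n_slices, fh = x.n_rows, fw = x.n_cols;
  if ((int)Whr.n_cols != D * 9 || (int)Whr.n_rows != D)
    Rcpp::stop("C-GRU kernels must be D x (D*9)");
  NetCfg c; c.D = D; c.fh = fh; c.fw = fw;
  Params P;
  P.Whr = Whr.t(); P.Wxr = Wxr.t(); P.Whz = Whz.t(); P.Wxz = Wxz.t();
  P.Wh = Wh.t(); P.Wx = Wx.t(); P.br = br; P.bz = bz; P.b = b;
  CgruCache C;
  cube hn = cgru_fw(x, h, P, c, &C);
  return Rcpp::List::create(Rcpp::Named("h") = hn,
                            Rcpp::Named("r") = C.r,
                            Rcpp::Named("z") = C.z);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_seq_forward(const arma::cube& frames,
                                    const arma::vec& theta,
                                    const Rcpp::List& cfg) {
  NetCfg c = parse_cfg(cfg);
  if ((int)frames.n_rows != c.H || (int)frames.n_cols != c.W)
    Rcpp::stop("frame size %dx%d != config %dx%d", (int)frames.n_rows,
               (int)frames.n_cols, c.H, c.W);
  const int K = frames.n_slices;
  Params P = walk_params(theta.memptr(), theta.n_elem, c);
  cube h(c.fh, c.fw, c.D, fill::zeros);
  Rcpp::NumericVector pred(K);
  for (int t = 0; t < K; ++t) {
    cube x = encoder_fw(frames.slice(t), P, c, nullptr);
    h = cgru_fw(x, h, P, c, nullptr);
    pred[t] = head_fw(h, P, c, nullptr);
  }
  return pred;
}

// [[Rcpp::export]]
Rcpp::List cpp_seq_grad(const arma::cube& frames, const arma::vec& y,
                        const arma::vec& theta, const Rcpp::List& cfg,
                        double lambda, int Tper, int Ncyc) {
  NetCfg c = parse_cfg(cfg);
  const int K = frames.n_slices;
  if ((int)y.n_elem != K) Rcpp::stop("label length != frame count");
  Params P = walk_params(theta.memptr(), theta.n_elem, c);
  Params G = zero_like(P);

  std::vector<std::vector<ConvCache>> enc(K);
  std::vector<CgruCache> gru(K);
  std::vector<FcCache> fc(K);
  vec pred(K);
  cube h(c.fh, c.fw, c.D, fill::zeros);
  for (int t = 0; t < K; ++t) {
    enc[t].resize(c.conv.size());
    cube x = encoder_fw(frames.slice(t), P, c, &enc[t]);
    h = cgru_fw(x, h, P, c, &gru[t]);
    pred(t) = head_fw(h, P, c, &fc[t]);
  }

  // loss = (1/K) sum (y - yhat)^2 + lambda * CL
  vec res = pred - y;
  const double mse = dot(res, res) / K;
  std::vector<std::pair<int,int>> pairs;
  cl_pairs(K, Tper, Ncyc, pairs);
  double S = 0.0;
  for (auto& pr : pairs) {
    const double d = pred(pr.second) - pred(pr.first);
    S += d * d;
  }
  const double cl = std::sqrt(S);
  const double loss = mse + lambda * cl;

  vec gy = (2.0 / K) * res;
  if (lambda > 0.0 && S > 0.0) {
    const double scale = lambda / cl;
    for (auto& pr : pairs) {
      const double d = pred(pr.second) - pred(pr.first);
      gy(pr.second) += scale * d;
      gy(pr.first) -= scale * d;
    }
  }

  cube gh(c.fh, c.fw, c.D, fill::zeros);
  for (int t = K - 1; t >= 0; --t) {
    gh += head_bw(gy(t), P, G, c, fc[t]);
    cube gx(c.fh, c.fw, (uword)c.D, fill::zeros);
    gh = cgru_bw(gh, P, G, c, gru[t], gx);
    encoder_bw(gx, P, G, c, enc[t]);
  }

  vec gtheta = flatten_params(G, theta.n_elem);
  return Rcpp::List::create(
      Rcpp::Named("pred") = Rcpp::NumericVector(pred.begin(), pred.end()),
      Rcpp::Named("loss") = loss, Rcpp::Named("mse") = mse,
      Rcpp::Named("cl") = cl,
      Rcpp::Named("grad") = Rcpp::NumericVector(gtheta.begin(), gtheta.end()));
}

// [[Rcpp::export]]
int cpp_theta_length(const Rcpp::List& cfg) {
  NetCfg c = parse_cfg(cfg);
  uword n = 0;
  for (auto& s : c.conv) n += (uword)s.cout * s.cin * s.k * s.k + s.cout;
  n += 6u * c.D * c.D * 9 + 3u * c.D;
  for (size_t i = 1; i < c.fc.size(); ++i)
    n += (uword)c.fc[i] * c.fc[i - 1] + c.fc[i];
  return (int)n;
}
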