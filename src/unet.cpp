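// Fully convolutional encoder-decoder density regressor.
//
// Feature maps are arma::fmat with one row per channel and one column per
// pixel of a halo-padded (H+2) x (W+2) canvas, samples stacked along
// columns: column index b*(H+2)*(W+2) + c*(H+2) + r.  The one-pixel zero
// halo lets 3x3 same-padding convolution run as nine accumulating
// single-precision GEMMs over shifted contiguous column ranges (implicit
// GEMM) with no im2col copying; halo columns are re-zeroed after each op.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

namespace {

struct Dims {
  int H, W, B;
  int Hp() const { return H + 2; }
  int Wp() const { return W + 2; }
  size_t hwp() const { return (size_t)Hp() * Wp(); }
  size_t ncols() const { return hwp() * B; }
  size_t nreal() const { return (size_t)H * W * B; }
};

// zero the halo columns (r = 0, r = Hp-1, c = 0, c = Wp-1 of every sample)
void zero_halo(fmat& x, const Dims& d) {
  const int C = x.n_rows, Hp = d.Hp(), Wp = d.Wp();
  for (int b = 0; b < d.B; ++b) {
    const size_t base = (size_t)b * d.hwp();
    std::memset(x.colptr(base), 0, sizeof(float) * C * Hp);
    std::memset(x.colptr(base + (size_t)(Wp - 1) * Hp), 0,
                sizeof(float) * C * Hp);
    for (int c = 1; c < Wp - 1; ++c) {
      std::memset(x.colptr(base + (size_t)c * Hp), 0, sizeof(float) * C);
      std::memset(x.colptr(base + (size_t)c * Hp + Hp - 1), 0,
                  sizeof(float) * C);
    }
  }
}

inline void sgemm_nn(int m, int n, int k, const float* a, int lda,
                     const float* b, int ldb, float beta, float* c, int ldc) {
  const float one = 1.0f;
  sgemm_("N", "N", &m, &n, &k, &one, a, &lda, b, &ldb, &beta, c, &ldc);
}

inline void sgemm_tn(int m, int n, int k, const float* a, int lda,
                     const float* b, int ldb, float beta, float* c, int ldc) {
  const float one = 1.0f;
  sgemm_("T", "N", &m, &n, &k, &one, a, &lda, b, &ldb, &beta, c, &ldc);
}

inline void sgemm_nt(int m, int n, int k, const float* a, int lda,
                     const float* b, int ldb, float beta, float* c, int ldc) {
  const float one = 1.0f;
  sgemm_("N", "T", &m, &n, &k, &one, a, &lda, b, &ldb, &beta, c, &ldc);
}

// out += W_tap * x shifted; blocked over columns so the out tile stays in
// cache across the nine taps.  W: cout x 9*cin, tap t = (dc+1)*3 + (dr+1).
void conv3_forward(const fmat& W, const fmat& x, const Dims& d, fmat& out) {
  const int cin = x.n_rows, cout = W.n_rows;
  const long N = (long)x.n_cols;
  out.zeros(cout, N);
  const long blk = 16384;
  for (long p0 = 0; p0 < N; p0 += blk) {
    const long p1 = std::min(N, p0 + blk);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        const int t = (dc + 1) * 3 + (dr + 1);
        const long s = (long)dc * d.Hp() + dr;
        const long lo = std::max(p0, -s), hi = std::min(p1, N - s);
        if (hi <= lo) continue;
        sgemm_nn(cout, (int)(hi - lo), cin, W.colptr((size_t)t * cin), cout,
                 x.colptr(lo + s), cin, 1.0f, out.colptr(lo), cout);
      }
  }
  zero_halo(out, d);
}

// dW += dout * x_shifted^T ; dx += W_tap^T * dout shifted
void conv3_backward(const fmat& W, fmat& dW, const fmat& x, const fmat& dout,
                    const Dims& d, fmat& dx) {
  const int cin = x.n_rows, cout = W.n_rows;
  const long N = (long)x.n_cols;
  dx.zeros(cin, N);
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      const int t = (dc + 1) * 3 + (dr + 1);
      const long s = (long)dc * d.Hp() + dr;
      const long lo = std::max(0L, -s), hi = std::min(N, N - s);
      if (hi <= lo) continue;
      // dW_tap (cout x cin) += dout.cols(lo,hi) * x.cols(lo+s,hi+s)^T
      sgemm_nt(cout, cin, (int)(hi - lo), dout.colptr(lo), cout,
               x.colptr(lo + s), cin, 1.0f, dW.colptr((size_t)t * cin), cout);
    }
  const long blk = 16384;
  for (long p0 = 0; p0 < N; p0 += blk) {
    const long p1 = std::min(N, p0 + blk);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        const int t = (dc + 1) * 3 + (dr + 1);
        const long s = (long)dc * d.Hp() + dr;
        // dx.col(p + s) += W_tap^T * dout.col(p)
        const long lo = std::max(p0, -s), hi = std::min(p1, N - s);
        if (hi <= lo) continue;
        sgemm_tn(cin, (int)(hi - lo), cout, W.colptr((size_t)t * cin), cout,
                 dout.colptr(lo), cout, 1.0f, dx.colptr(lo + s), cin);
      }
  }
  zero_halo(dx, d);
}

// ---------------------------------------------------------------------------

struct Param {
  fmat w, g, m, v;
  void init(int nr, int nc) {
    w.zeros(nr, nc); g.zeros(nr, nc); m.zeros(nr, nc); v.zeros(nr, nc);
  }
  void step(float lr, float b1, float b2, float eps, float wd, float c1,
            float c2) {
    g += wd * w;
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * square(g);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
};

// conv3x3 (no bias) + batch norm + ReLU
struct ConvBlock {
  int cin, cout;
  Param W;            // cout x 9*cin
  Param gamma, beta;  // cout x 1
  fvec run_mean, run_var;
  // saved for backward
  fmat x_in, xhat, y;
  fvec istd;
  Dims dims;

  void init(int ci, int co) {
    cin = ci; cout = co;
    W.init(co, 9 * ci);
    gamma.init(co, 1); beta.init(co, 1);
    run_mean.zeros(co); run_var.ones(co);
  }

  fmat forward(const fmat& x, const Dims& d, bool training, float momentum,
               bool keep) {
    fmat z;
    conv3_forward(W.w, x, d, z);
    const double nreal = (double)d.nreal();
    fvec mu(cout), var(cout);
    if (training) {
      mu = conv_to<fvec>::from(sum(z, 1)) / (float)nreal;
      z.each_col() -= mu;
      zero_halo(z, d);  // halos became -mu
      var = conv_to<fvec>::from(sum(square(z), 1)) / (float)nreal;
      run_mean = (1.0f - momentum) * run_mean + momentum * mu;
      run_var = (1.0f - momentum) * run_var + momentum * var;
    } else {
      z.each_col() -= run_mean;
      var = run_var;
    }
    fvec is = 1.0f / sqrt(var + 1e-5f);
    z.each_col() %= is;
    if (keep) { x_in = x; xhat = z; istd = is; dims = d; }
    z.each_col() %= gamma.w.col(0);
    z.each_col() += beta.w.col(0);
    z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    zero_halo(z, d);
    if (keep) y = z;
    return z;
  }

  // dy is consumed; returns dx
  fmat backward(fmat dy) {
    const float n = (float)dims.nreal();
    // ReLU mask; y has zero halos so dy halos are zeroed here too
    float* pd = dy.memptr();
    const float* py = y.memptr();
    const size_t nn = dy.n_elem;
    for (size_t i = 0; i < nn; ++i)
      if (py[i] <= 0.0f) pd[i] = 0.0f;
    // batch-norm backward (sums over real pixels; halo terms vanish)
    fvec sdy = conv_to<fvec>::from(sum(dy, 1));
    fvec sdyx = conv_to<fvec>::from(sum(dy % xhat, 1));
    gamma.g += sdyx;
    beta.g += sdy;
    fmat dz = std::move(dy);
    dz *= n;
    {
      fmat corr = xhat;
      corr.each_col() %= sdyx;
      dz -= corr;
    }
    dz.each_col() -= sdy;
    dz.each_col() %= gamma.w.col(0) % istd / n;
    zero_halo(dz, dims);
    fmat dx;
    conv3_backward(W.w, W.g, x_in, dz, dims, dx);
    x_in.reset(); xhat.reset(); y.reset();
    return dx;
  }

  void release() { x_in.reset(); xhat.reset(); y.reset(); }
};

// 2x2 stride-2 transposed convolution, with bias
struct UpConv {
  int cin, cout;
  Param W;  // cout x 4*cin, tap t = dc*2 + dr
  Param b;  // cout x 1
  fmat x_in;
  Dims dims_in;

  void init(int ci, int co) {
    cin = ci; cout = co;
    W.init(co, 4 * ci);
    b.init(co, 1);
  }

  // x: cin x padded(H, W, B) -> cout x padded(2H, 2W, B)
  fmat forward(const fmat& x, const Dims& d, bool keep) {
    if (keep) { x_in = x; dims_in = d; }
    const Dims o{2 * d.H, 2 * d.W, d.B};
    fmat out(cout, o.ncols(), fill::zeros);
    const int Hp = d.Hp(), Hp2 = o.Hp();
    for (int t = 0; t < 4; ++t) {
      const int dr = t % 2, dc = t / 2;
      fmat yt = W.w.cols(t * cin, (t + 1) * cin - 1) * x;
      for (int bb = 0; bb < d.B; ++bb)
        for (int c = 1; c <= d.W; ++c) {
          const float* src = yt.colptr((size_t)bb * d.hwp() +
                                       (size_t)c * Hp + 1);
          float* dst = out.colptr((size_t)bb * o.hwp() +
                                  (size_t)(2 * (c - 1) + dc + 1) * Hp2 +
                                  dr + 1);
          for (int r = 0; r < d.H; ++r) {
            float* dp = dst + (size_t)2 * r * cout;
            const float* sp = src + (size_t)r * cout;
            for (int ch = 0; ch < cout; ++ch) dp[ch] += sp[ch];
          }
        }
    }
    // bias on real pixels only
    for (int bb = 0; bb < o.B; ++bb)
      for (int c = 1; c <= o.W; ++c) {
        float* dst = out.colptr((size_t)bb * o.hwp() + (size_t)c * o.Hp() + 1);
        const float* pb = b.w.colptr(0);
        for (int r = 0; r < o.H; ++r) {
          float* dp = dst + (size_t)r * cout;
          for (int ch = 0; ch < cout; ++ch) dp[ch] += pb[ch];
        }
      }
    return out;
  }

  fmat backward(const fmat& dy) {
    const Dims& d = dims_in;
    const Dims o{2 * d.H, 2 * d.W, d.B};
    const int Hp = d.Hp(), Hp2 = o.Hp();
    b.g += sum(dy, 1);
    fmat dx(cin, d.ncols(), fill::zeros);
    fmat dyt(cout, d.ncols());
    for (int t = 0; t < 4; ++t) {
      const int dr = t % 2, dc = t / 2;
      dyt.zeros();
      for (int bb = 0; bb < d.B; ++bb)
        for (int c = 1; c <= d.W; ++c) {
          float* dst = dyt.colptr((size_t)bb * d.hwp() + (size_t)c * Hp + 1);
          const float* src = dy.colptr((size_t)bb * o.hwp() +
                                       (size_t)(2 * (c - 1) + dc + 1) * Hp2 +
                                       dr + 1);
          for (int r = 0; r < d.H; ++r)
            std::memcpy(dst + (size_t)r * cout, src + (size_t)2 * r * cout,
                        sizeof(float) * cout);
        }
      W.g.cols(t * cin, (t + 1) * cin - 1) += dyt * x_in.t();
      dx += W.w.cols(t * cin, (t + 1) * cin - 1).t() * dyt;
    }
    zero_halo(dx, d);
    x_in.reset();
    return dx;
  }

  void release() { x_in.reset(); }
};

// final 1x1 conv + ReLU
struct Head {
  int cin;
  Param W;  // 1 x cin
  Param b;  // 1 x 1
  fmat x_in, y;
  Dims dims;

  void init(int ci) { cin = ci; W.init(1, ci); b.init(1, 1); }

  fmat forward(const fmat& x, const Dims& d, bool keep) {
    fmat z = W.w * x;
    z += b.w(0, 0);
    z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    zero_halo(z, d);
    if (keep) { x_in = x; y = z; dims = d; }
    return z;
  }

  fmat backward(fmat dy) {
    float* pd = dy.memptr();
    const float* py = y.memptr();
    for (size_t i = 0; i < dy.n_elem; ++i)
      if (py[i] <= 0.0f) pd[i] = 0.0f;
    W.g += dy * x_in.t();
    b.g(0, 0) += accu(dy);
    fmat dx = W.w.t() * dy;
    x_in.reset(); y.reset();
    return dx;
  }

  void release() { x_in.reset(); y.reset(); }
};

struct UNet {
  int depth, base;
  std::vector<ConvBlock> blocks;  // 2*depth enc + 2 bottleneck + 2*depth dec
  std::vector<UpConv> ups;        // ups[s] decodes back to encoder stage s
  Head head;
  std::vector<umat> pool_idx;
  std::vector<fmat> skips;
  std::vector<Dims> skip_dims;
  int adam_t = 0;

  UNet(int d, int b) : depth(d), base(b) {
    blocks.resize(4 * d + 2);
    ups.resize(d);
    int ci = 3;
    for (int s = 0; s < d; ++s) {
      const int co = b << s;
      blocks[2 * s].init(ci, co);
      blocks[2 * s + 1].init(co, co);
      ci = co;
    }
    const int cb = b << d;
    blocks[2 * d].init(ci, cb);
    blocks[2 * d + 1].init(cb, cb);
    for (int s = d - 1; s >= 0; --s) {
      const int co = b << s;
      ups[s].init(co * 2, co);
      const int bi = 2 * d + 2 + 2 * (d - 1 - s);
      blocks[bi].init(co * 2, co);
      blocks[bi + 1].init(co, co);
    }
    head.init(b);
  }

  static fmat maxpool(const fmat& x, const Dims& d, Dims& dout, umat& idx,
                      bool keep) {
    const int C = x.n_rows, Hp = d.Hp();
    dout = {d.H / 2, d.W / 2, d.B};
    const int Hp2 = dout.Hp();
    fmat out(C, dout.ncols(), fill::zeros);
    if (keep) idx.zeros(C, dout.ncols());  // halo columns scatter to col 0
    for (int b = 0; b < d.B; ++b)
      for (int c = 0; c < dout.W; ++c)
        for (int r = 0; r < dout.H; ++r) {
          const size_t oc =
              (size_t)b * dout.hwp() + (size_t)(c + 1) * Hp2 + r + 1;
          size_t cand[4];
          const size_t ibase = (size_t)b * d.hwp();
          cand[0] = ibase + (size_t)(2 * c + 1) * Hp + 2 * r + 1;
          cand[1] = cand[0] + 1;
          cand[2] = cand[0] + Hp;
          cand[3] = cand[2] + 1;
          const float* p0 = x.colptr(cand[0]);
          const float* p1 = x.colptr(cand[1]);
          const float* p2 = x.colptr(cand[2]);
          const float* p3 = x.colptr(cand[3]);
          float* po = out.colptr(oc);
          uword* pi = keep ? idx.colptr(oc) : nullptr;
          for (int ch = 0; ch < C; ++ch) {
            float best = p0[ch];
            size_t bi = cand[0];
            if (p1[ch] > best) { best = p1[ch]; bi = cand[1]; }
            if (p2[ch] > best) { best = p2[ch]; bi = cand[2]; }
            if (p3[ch] > best) { best = p3[ch]; bi = cand[3]; }
            po[ch] = best;
            if (pi) pi[ch] = bi;
          }
        }
    return out;
  }

  fmat forward(const fmat& input, Dims d, bool training, float momentum,
               bool keep) {
    pool_idx.assign(depth, umat());
    skips.assign(depth, fmat());
    skip_dims.assign(depth, Dims{0, 0, 0});
    fmat x = input;
    for (int s = 0; s < depth; ++s) {
      x = blocks[2 * s].forward(x, d, training, momentum, keep);
      x = blocks[2 * s + 1].forward(x, d, training, momentum, keep);
      skips[s] = x;
      skip_dims[s] = d;
      Dims dn;
      x = maxpool(x, d, dn, pool_idx[s], keep);
      d = dn;
    }
    x = blocks[2 * depth].forward(x, d, training, momentum, keep);
    x = blocks[2 * depth + 1].forward(x, d, training, momentum, keep);
    for (int s = depth - 1; s >= 0; --s) {
      x = ups[s].forward(x, d, keep);
      d = skip_dims[s];
      x = join_cols(x, skips[s]);
      if (!keep) skips[s].reset();
      const int bi = 2 * depth + 2 + 2 * (depth - 1 - s);
      x = blocks[bi].forward(x, d, training, momentum, keep);
      x = blocks[bi + 1].forward(x, d, training, momentum, keep);
    }
    fmat out = head.forward(x, d, keep);
    if (!keep) release_saved();
    return out;
  }

  fmat backward(const fmat& dpred) {
    fmat dx = head.backward(dpred);
    std::vector<fmat> dskips(depth);
    // decoder stages, shallowest (s = 0, last in forward) first
    for (int s = 0; s <= depth - 1; ++s) {
      const int bi = 2 * depth + 2 + 2 * (depth - 1 - s);
      dx = blocks[bi + 1].backward(std::move(dx));
      dx = blocks[bi].backward(std::move(dx));
      const int cup = ups[s].cout;
      dskips[s] = dx.rows(cup, dx.n_rows - 1);
      fmat dup = dx.rows(0, cup - 1);
      dx = ups[s].backward(dup);
    }
    dx = blocks[2 * depth + 1].backward(std::move(dx));
    dx = blocks[2 * depth].backward(std::move(dx));
    // encoder stages, deepest first
    for (int s = depth - 1; s >= 0; --s) {
      const Dims& dsk = skip_dims[s];
      const umat& idx = pool_idx[s];
      fmat dpool(dskips[s].n_rows, dsk.ncols(), fill::zeros);
      const size_t nch = idx.n_rows;
      for (size_t j = 0; j < idx.n_cols; ++j) {
        const uword* pi = idx.colptr(j);
        const float* pg = dx.colptr(j);
        for (size_t ch = 0; ch < nch; ++ch) dpool.at(ch, pi[ch]) += pg[ch];
      }
      dpool += dskips[s];
      dskips[s].reset();
      pool_idx[s].reset();
      dx = blocks[2 * s + 1].backward(std::move(dpool));
      dx = blocks[2 * s].backward(std::move(dx));
      skips[s].reset();
    }
    return dx;
  }

  void release_saved() {
    for (auto& b : blocks) b.release();
    for (auto& u : ups) u.release();
    head.release();
    pool_idx.clear(); skips.clear(); skip_dims.clear();
  }

  void zero_grad() {
    for (auto& b : blocks) { b.W.g.zeros(); b.gamma.g.zeros(); b.beta.g.zeros(); }
    for (auto& u : ups) { u.W.g.zeros(); u.b.g.zeros(); }
    head.W.g.zeros(); head.b.g.zeros();
  }

  void step(float lr, float b1, float b2, float eps, float wd) {
    ++adam_t;
    const float c1 = 1.0f - std::pow(b1, (float)adam_t);
    const float c2 = 1.0f - std::pow(b2, (float)adam_t);
    for (auto& bl : blocks) {
      bl.W.step(lr, b1, b2, eps, wd, c1, c2);
      bl.gamma.step(lr, b1, b2, eps, 0.0f, c1, c2);
      bl.beta.step(lr, b1, b2, eps, 0.0f, c1, c2);
    }
    for (auto& u : ups) {
      u.W.step(lr, b1, b2, eps, wd, c1, c2);
      u.b.step(lr, b1, b2, eps, 0.0f, c1, c2);
    }
    head.W.step(lr, b1, b2, eps, wd, c1, c2);
    head.b.step(lr, b1, b2, eps, 0.0f, c1, c2);
  }
};

// R array (H, W, C, B) -> padded feature matrix (C, (H+2)*(W+2)*B)
fmat r_to_feat(const Rcpp::NumericVector& arr, int C, const Dims& d) {
  fmat x(C, d.ncols(), fill::zeros);
  const double* p = arr.begin();
  const size_t hw = (size_t)d.H * d.W;
  const int Hp = d.Hp();
  for (int b = 0; b < d.B; ++b)
    for (int ch = 0; ch < C; ++ch) {
      const double* src = p + ((size_t)b * C + ch) * hw;
      for (int c = 0; c < d.W; ++c)
        for (int r = 0; r < d.H; ++r)
          x(ch, (size_t)b * d.hwp() + (size_t)(c + 1) * Hp + r + 1) =
              (float)src[(size_t)c * d.H + r];
    }
  return x;
}

Rcpp::NumericVector feat_to_r(const fmat& y, const Dims& d) {
  Rcpp::NumericVector out((R_xlen_t)d.nreal());
  out.attr("dim") = Rcpp::IntegerVector::create(d.H, d.W, d.B);
  const int Hp = d.Hp();
  double* dst = out.begin();
  for (int b = 0; b < d.B; ++b)
    for (int c = 0; c < d.W; ++c)
      for (int r = 0; r < d.H; ++r)
        dst[(size_t)b * d.H * d.W + (size_t)c * d.H + r] =
            y(0, (size_t)b * d.hwp() + (size_t)(c + 1) * Hp + r + 1);
  return out;
}

void set_param(Param& p, const Rcpp::NumericMatrix& m) {
  p.w.set_size(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) p.w(i, j) = (float)m(i, j);
}

Rcpp::NumericMatrix get_param(const Param& p) {
  Rcpp::NumericMatrix m(p.w.n_rows, p.w.n_cols);
  for (size_t j = 0; j < p.w.n_cols; ++j)
    for (size_t i = 0; i < p.w.n_rows; ++i) m(i, j) = p.w(i, j);
  return m;
}

Rcpp::NumericMatrix get_grad(const Param& p) {
  Rcpp::NumericMatrix m(p.g.n_rows, p.g.n_cols);
  for (size_t j = 0; j < p.g.n_cols; ++j)
    for (size_t i = 0; i < p.g.n_rows; ++i) m(i, j) = p.g(i, j);
  return m;
}

}  // namespace

// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_unet_create")]]
SEXP cpp_unet_create(int depth, int base) {
  Rcpp::XPtr<UNet> ptr(new UNet(depth, base), true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_unet_set_weights")]]
void cpp_unet_set_weights(SEXP net_, Rcpp::List w) {
  Rcpp::XPtr<UNet> net(net_);
  const int d = net->depth;
  for (int i = 0; i < 4 * d + 2; ++i) {
    Rcpp::List bl = w["block" + std::to_string(i)];
    set_param(net->blocks[i].W, Rcpp::as<Rcpp::NumericMatrix>(bl["W"]));
    set_param(net->blocks[i].gamma,
              Rcpp::as<Rcpp::NumericMatrix>(bl["gamma"]));
    set_param(net->blocks[i].beta, Rcpp::as<Rcpp::NumericMatrix>(bl["beta"]));
    Rcpp::NumericVector rm = bl["run_mean"], rv = bl["run_var"];
    net->blocks[i].run_mean =
        conv_to<fvec>::from(Rcpp::as<std::vector<double>>(rm));
    net->blocks[i].run_var =
        conv_to<fvec>::from(Rcpp::as<std::vector<double>>(rv));
  }
  for (int s = 0; s < d; ++s) {
    Rcpp::List ul = w["up" + std::to_string(s)];
    set_param(net->ups[s].W, Rcpp::as<Rcpp::NumericMatrix>(ul["W"]));
    set_param(net->ups[s].b, Rcpp::as<Rcpp::NumericMatrix>(ul["b"]));
  }
  Rcpp::List hl = w["head"];
  set_param(net->head.W, Rcpp::as<Rcpp::NumericMatrix>(hl["W"]));
  set_param(net->head.b, Rcpp::as<Rcpp::NumericMatrix>(hl["b"]));
  net->adam_t = Rcpp::as<int>(w["adam_t"]);
}

// [[Rcpp::export(name = ".cpp_unet_get_weights")]]
Rcpp::List cpp_unet_get_weights(SEXP net_) {
  Rcpp::XPtr<UNet> net(net_);
  Rcpp::List out;
  const int d = net->depth;
  for (int i = 0; i < 4 * d + 2; ++i) {
    const ConvBlock& b = net->blocks[i];
    out["block" + std::to_string(i)] = Rcpp::List::create(
        Rcpp::Named("W") = get_param(b.W),
        Rcpp::Named("gamma") = get_param(b.gamma),
        Rcpp::Named("beta") = get_param(b.beta),
        Rcpp::Named("run_mean") =
            Rcpp::NumericVector(b.run_mean.begin(), b.run_mean.end()),
        Rcpp::Named("run_var") =
            Rcpp::NumericVector(b.run_var.begin(), b.run_var.end()));
  }
  for (int s = 0; s < d; ++s)
    out["up" + std::to_string(s)] = Rcpp::List::create(
        Rcpp::Named("W") = get_param(net->ups[s].W),
        Rcpp::Named("b") = get_param(net->ups[s].b));
  out["head"] = Rcpp::List::create(Rcpp::Named("W") = get_param(net->head.W),
                                   Rcpp::Named("b") = get_param(net->head.b));
  out["adam_t"] = net->adam_t;
  return out;
}

// [[Rcpp::export(name = ".cpp_unet_get_grads")]]
Rcpp::List cpp_unet_get_grads(SEXP net_) {
  Rcpp::XPtr<UNet> net(net_);
  Rcpp::List out;
  const int d = net->depth;
  for (int i = 0; i < 4 * d + 2; ++i)
    out["block" + std::to_string(i)] = Rcpp::List::create(
        Rcpp::Named("W") = get_grad(net->blocks[i].W),
        Rcpp::Named("gamma") = get_grad(net->blocks[i].gamma),
        Rcpp::Named("beta") = get_grad(net->blocks[i].beta));
  for (int s = 0; s < d; ++s)
    out["up" + std::to_string(s)] = Rcpp::List::create(
        Rcpp::Named("W") = get_grad(net->ups[s].W),
        Rcpp::Named("b") = get_grad(net->ups[s].b));
  out["head"] = Rcpp::List::create(Rcpp::Named("W") = get_grad(net->head.W),
                                   Rcpp::Named("b") = get_grad(net->head.b));
  return out;
}

// [[Rcpp::export(name = ".cpp_unet_forward")]]
Rcpp::NumericVector cpp_unet_forward(SEXP net_, Rcpp::NumericVector x,
                                     bool training, double momentum,
                                     bool keep) {
  Rcpp::XPtr<UNet> net(net_);
  Rcpp::IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) Rcpp::stop("input must be a (H, W, C, B) array");
  Dims d = {dm[0], dm[1], dm[3]};
  if (dm[2] != 3) Rcpp::stop("input must have 3 channels");
  const int div = 1 << net->depth;
  if (d.H % div != 0 || d.W % div != 0)
    Rcpp::stop("input height and width must be divisible by %d", div);
  fmat xf = r_to_feat(x, 3, d);
  fmat y = net->forward(xf, d, training, (float)momentum, keep);
  return feat_to_r(y, d);
}

// [[Rcpp::export(name = ".cpp_unet_backward")]]
void cpp_unet_backward(SEXP net_, Rcpp::NumericVector grad) {
  Rcpp::XPtr<UNet> net(net_);
  Rcpp::IntegerVector dm = grad.attr("dim");
  if (dm.size() != 3) Rcpp::stop("gradient must be a (H, W, B) array");
  Dims d = {dm[0], dm[1], dm[2]};
  fmat g(1, d.ncols(), fill::zeros);
  const int Hp = d.Hp();
  for (int b = 0; b < d.B; ++b)
    for (int c = 0; c < d.W; ++c)
      for (int r = 0; r < d.H; ++r)
        g(0, (size_t)b * d.hwp() + (size_t)(c + 1) * Hp + r + 1) =
            (float)grad[(size_t)b * d.H * d.W + (size_t)c * d.H + r];
  net->backward(g);
}

// [[Rcpp::export(name = ".cpp_unet_zero_grad")]]
void cpp_unet_zero_grad(SEXP net_) {
  Rcpp::XPtr<UNet> net(net_);
  net->zero_grad();
}

// [[Rcpp::export(name = ".cpp_unet_step")]]
void cpp_unet_step(SEXP net_, double lr, double beta1, double beta2,
                   double eps, double weight_decay) {
  Rcpp::XPtr<UNet> net(net_);
  net->step((float)lr, (float)beta1, (float)beta2, (float)eps,
            (float)weight_decay);
}

// ---------------------------------------------------------------------------
// image rotation (bilinear / nearest) used by training-time augmentation

// [[Rcpp::export(name = ".cpp_rotate_image")]]
Rcpp::NumericVector cpp_rotate_image(Rcpp::NumericVector img, double angle,
                                     bool bilinear, double fill) {
  Rcpp::IntegerVector dm = img.attr("dim");
  if (dm.size() != 3) Rcpp::stop("image must be an (H, W, C) array");
  const int H = dm[0], W = dm[1], C = dm[2];
  const double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  const double ca = std::cos(angle), sa = std::sin(angle);
  Rcpp::NumericVector out((size_t)H * W * C);
  out.attr("dim") = dm;
  const double* src = img.begin();
  double* dst = out.begin();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      // inverse rotation: source position for output (r, c)
      const double dr = r - cr, dc = c - cc;
      const double sr = ca * dr + sa * dc + cr;
      const double sc = -sa * dr + ca * dc + cc;
      for (int ch = 0; ch < C; ++ch) {
        double val = fill;
        if (bilinear) {
          if (sr >= 0 && sr <= H - 1 && sc >= 0 && sc <= W - 1) {
            const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
            const int r1 = std::min(r0 + 1, H - 1),
                      c1 = std::min(c0 + 1, W - 1);
            const double fr = sr - r0, fc = sc - c0;
            const size_t off = (size_t)ch * H * W;
            const double v00 = src[off + (size_t)c0 * H + r0];
            const double v10 = src[off + (size_t)c0 * H + r1];
            const double v01 = src[off + (size_t)c1 * H + r0];
            const double v11 = src[off + (size_t)c1 * H + r1];
            val = (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
                  (1 - fr) * fc * v01 + fr * fc * v11;
          }
        } else {
          const long ri = std::lround(sr), ci = std::lround(sc);
          if (ri >= 0 && ri < H && ci >= 0 && ci < W)
            val = src[(size_t)ch * H * W + (size_t)ci * H + ri];
        }
        dst[(size_t)ch * H * W + (size_t)c * H + r] = val;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// peak extraction: threshold, plateau-aware local maxima, greedy suppression

// [[Rcpp::export(name = ".cpp_extract_peaks")]]
Rcpp::List cpp_extract_peaks(Rcpp::NumericMatrix den, double gamma,
                             double delta) {
  const int H = den.nrow(), W = den.ncol();
  std::vector<double> z((size_t)H * W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double v = den(r, c);
      z[(size_t)c * H + r] = (v < gamma) ? 0.0 : v;
    }
  auto at = [&](int r, int c) { return z[(size_t)c * H + r]; };
  // candidate = pixel with positive value >= gamma and no strictly greater
  // 8-neighbour
  std::vector<char> cand((size_t)H * W, 0);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const double v = at(r, c);
      if (v <= 0.0 || v < gamma) continue;
      bool ok = true;
      for (int dc = -1; dc <= 1 && ok; ++dc)
        for (int dr = -1; dr <= 1 && ok; ++dr) {
          if (dr == 0 && dc == 0) continue;
          const int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (at(rr, cc) > v) ok = false;
        }
      if (ok) cand[(size_t)c * H + r] = 1;
    }
  // plateau dedup: 8-connected components of equal-valued candidates keep
  // only their top-left (min row, then min col) pixel
  std::vector<int> comp((size_t)H * W, -1);
  std::vector<std::array<int, 3>> reps;
  std::vector<double> repval;
  int ncomp = 0;
  std::vector<std::pair<int, int>> stack;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      const size_t i0 = (size_t)c0 * H + r0;
      if (!cand[i0] || comp[i0] >= 0) continue;
      const double v = at(r0, c0);
      const int id = ncomp++;
      int br = r0, bc = c0;
      comp[i0] = id;
      stack.clear();
      stack.push_back({r0, c0});
      while (!stack.empty()) {
        auto rc = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int rr = rc.first + dr, cc = rc.second + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            const size_t ii = (size_t)cc * H + rr;
            if (!cand[ii] || comp[ii] >= 0 || at(rr, cc) != v) continue;
            comp[ii] = id;
            if (rr < br || (rr == br && cc < bc)) { br = rr; bc = cc; }
            stack.push_back({rr, cc});
          }
      }
      reps.push_back({br, bc, id});
      repval.push_back(v);
    }
  // sort by descending value, then ascending (row, col)
  std::vector<int> ord(reps.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (repval[a] != repval[b]) return repval[a] > repval[b];
    if (reps[a][0] != reps[b][0]) return reps[a][0] < reps[b][0];
    return reps[a][1] < reps[b][1];
  });
  // greedy minimum-distance suppression (< delta suppressed)
  std::vector<int> keep;
  const double d2 = delta * delta;
  for (int i : ord) {
    bool ok = true;
    for (int j : keep) {
      const double dr = reps[i][0] - reps[j][0], dc = reps[i][1] - reps[j][1];
      if (dr * dr + dc * dc < d2) { ok = false; break; }
    }
    if (ok) keep.push_back(i);
  }
  Rcpp::IntegerVector prow(keep.size()), pcol(keep.size());
  Rcpp::NumericVector pval(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    prow[i] = reps[keep[i]][0];
    pcol[i] = reps[keep[i]][1];
    pval[i] = repval[keep[i]];
  }
  return Rcpp::List::create(Rcpp::Named("row") = prow,
                            Rcpp::Named("col") = pcol,
                            Rcpp::Named("value") = pval);
}
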