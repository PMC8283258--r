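// Minimal float32 CNN training engine: 3x3 convolutions (pad 1, stride 1),
// 2x2 max pooling, dense layers, sigmoid output with focal loss, SGD with
// momentum.  Layout conventions (mirrored by the R wrappers):
//   * images are H x W, column-major, pixel linear index p = y + H*x
//   * a batch activation is an (B*H*W) x C matrix; sample b occupies rows
//     [b*H*W, (b+1)*H*W)
//   * conv weights are (9*C_in) x C_out; row index = k*C_in + c with
//     k = (dx+1)*3 + (dy+1), dx,dy in {-1,0,1}
//   * dense weights are F x n_out with flattened feature index
//     f = c*H*W + p (channel-major blocks)
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

enum { L_AVGPOOL = 1, L_CONV = 2, L_MAXPOOL = 3, L_DENSE = 4 };

struct LayerDims { int h_in, w_in, c_in, h_out, w_out, c_out; };

static std::vector<LayerDims> layer_dims(const IntegerMatrix& layers, int H, int W) {
  std::vector<LayerDims> d(layers.nrow());
  int h = H, w = W, c = 1;
  for (int i = 0; i < layers.nrow(); ++i) {
    int type = layers(i, 0);
    d[i].h_in = h; d[i].w_in = w; d[i].c_in = c;
    if (type == L_AVGPOOL) {
      int ky = layers(i, 1), kx = layers(i, 2);
      if (kx == 0) kx = ky;
      if (i != 0) stop("average-pool stem only supported as first layer");
      if (h % ky || w % kx) stop("avgpool: dims not divisible by kernel");
      h /= ky; w /= kx;
    } else if (type == L_CONV) {
      if (layers(i, 1) != c) stop("conv layer %d: channel mismatch", i + 1);
      c = layers(i, 2);
    } else if (type == L_MAXPOOL) {
      if (h % 2 || w % 2) stop("maxpool: odd dims");
      h /= 2; w /= 2;
    } else if (type == L_DENSE) {
      if (layers(i, 1) != h * w * c) stop("dense layer %d: input size mismatch", i + 1);
      h = 1; w = 1; c = layers(i, 2);
    } else stop("unknown layer type %d", type);
    d[i].h_out = h; d[i].w_out = w; d[i].c_out = c;
  }
  return d;
}

static void im2col(const fmat& A, int B, int H, int W, fmat& col) {
  const int C = A.n_cols, HW = H * W;
  col.zeros(A.n_rows, 9 * C);
  for (int k = 0; k < 9; ++k) {
    const int dx = k / 3 - 1, dy = k % 3 - 1;
    const int y0 = std::max(0, -dy);
    const int len = H - std::abs(dy);
    for (int c = 0; c < C; ++c) {
      const float* src = A.colptr(c);
      float* dst = col.colptr(k * C + c);
      for (int b = 0; b < B; ++b) {
        const int base = b * HW;
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          std::memcpy(dst + base + x * H + y0,
                      src + base + sx * H + y0 + dy,
                      len * sizeof(float));
        }
      }
    }
  }
}

static void col2im(const fmat& dcol, int B, int H, int W, int C, fmat& dA) {
  dA.zeros(dcol.n_rows, C);
  const int HW = H * W;
  for (int k = 0; k < 9; ++k) {
    const int dx = k / 3 - 1, dy = k % 3 - 1;
    const int y0 = std::max(0, -dy);
    const int len = H - std::abs(dy);
    for (int c = 0; c < C; ++c) {
      const float* src = dcol.colptr(k * C + c);
      float* dst = dA.colptr(c);
      for (int b = 0; b < B; ++b) {
        const int base = b * HW;
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          const float* s = src + base + x * H + y0;
          float* d = dst + base + sx * H + y0 + dy;
          for (int i = 0; i < len; ++i) d[i] += s[i];
        }
      }
    }
  }
}

static void maxpool2(const fmat& A, int B, int H, int W, fmat& out, arma::umat& idx) {
  const int C = A.n_cols, HW = H * W;
  const int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo;
  out.set_size((arma::uword)B * HWo, C);
  idx.set_size((arma::uword)B * HWo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    arma::uword* ix = idx.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int bi = b * HW, bo = b * HWo;
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          int r0 = bi + (2 * xo) * H + 2 * yo;
          int cand[4] = { r0, r0 + 1, r0 + H, r0 + H + 1 };
          int best = cand[0];
          for (int j = 1; j < 4; ++j) if (src[cand[j]] > src[best]) best = cand[j];
          dst[bo + xo * Ho + yo] = src[best];
          ix[bo + xo * Ho + yo] = best;
        }
      }
    }
  }
}

static fmat avgpool_stem(const fmat& X1, int H, int W, int ky, int kx) {
  // X1: (H*W) x n, one column per sample; returns (H/ky * W/kx) x n
  const int Ho = H / ky, Wo = W / kx;
  fmat out(Ho * Wo, X1.n_cols);
  const float inv = 1.0f / (ky * kx);
  for (arma::uword s = 0; s < X1.n_cols; ++s) {
    const float* src = X1.colptr(s);
    float* dst = out.colptr(s);
    for (int xo = 0; xo < Wo; ++xo)
      for (int yo = 0; yo < Ho; ++yo) {
        float acc = 0.0f;
        for (int dx = 0; dx < kx; ++dx)
          for (int dy = 0; dy < ky; ++dy)
            acc += src[(xo * kx + dx) * H + yo * ky + dy];
        dst[xo * Ho + yo] = acc * inv;
      }
  }
  return out;
}

struct Cache {
  std::vector<fmat> act;   // output activation of each layer
  std::vector<fmat> col;   // im2col matrices for conv layers
  std::vector<arma::umat> poolidx;
  std::vector<fmat> dense_in;
};

// Forward pass from layer `start` on activation A ((B*H*W) x C).
// Returns logits (n_out x B) for a net ending in a dense layer.
static fmat forward(const IntegerMatrix& layers, const std::vector<LayerDims>& dims,
                    const std::vector<fmat>& Wts, const std::vector<fvec>& bs,
                    const std::vector<int>& wslot,
                    fmat A, int B, int start, bool keep, Cache* cache) {
  fmat dense_x;           // F x B once flattened
  bool flat = false;
  if (cache) {
    cache->act.assign(layers.nrow(), fmat());
    cache->col.assign(layers.nrow(), fmat());
    cache->poolidx.assign(layers.nrow(), arma::umat());
    cache->dense_in.assign(layers.nrow(), fmat());
  }
  for (int i = start; i < layers.nrow(); ++i) {
    const int type = layers(i, 0);
    const LayerDims& d = dims[i];
    if (type == L_CONV) {
      fmat col;
      im2col(A, B, d.h_in, d.w_in, col);
      fmat Z = col * Wts[wslot[i]];
      Z.each_row() += bs[wslot[i]].t();
      Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      if (cache && keep) cache->col[i] = std::move(col);
      A = std::move(Z);
    } else if (type == L_MAXPOOL) {
      fmat out; arma::umat idx;
      maxpool2(A, B, d.h_in, d.w_in, out, idx);
      if (cache && keep) cache->poolidx[i] = std::move(idx);
      A = std::move(out);
    } else if (type == L_DENSE) {
      if (!flat) {
        const int HW = d.h_in * d.w_in;
        const int C = d.c_in, F = HW * C;
        dense_x.set_size(F, B);
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < C; ++c)
            std::memcpy(dense_x.colptr(b) + c * HW, A.colptr(c) + b * HW,
                        HW * sizeof(float));
        flat = true;
      }
      if (cache && keep) cache->dense_in[i] = dense_x;
      fmat Z = Wts[wslot[i]].t() * dense_x;
      Z.each_col() += bs[wslot[i]];
      if (layers(i, 3)) Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      dense_x = std::move(Z);
    } else stop("unexpected layer in forward");
    if (cache && keep && type != L_DENSE) cache->act[i] = A;
    if (cache && keep && type == L_DENSE) cache->act[i] = dense_x;
  }
  return dense_x;
}

static void backward(const IntegerMatrix& layers, const std::vector<LayerDims>& dims,
                     const std::vector<fmat>& Wts, const std::vector<int>& wslot,
                     const Cache& cache, const fmat& A0, int B, int start,
                     fmat dZ, std::vector<fmat>& gW, std::vector<fvec>& gb) {
  // dZ: gradient wrt the final dense pre-activation (n_out x B)
  bool in_dense = true;
  fmat dA;                       // conv-domain gradient once unflattened
  for (int i = layers.nrow() - 1; i >= start; --i) {
    const int type = layers(i, 0);
    const LayerDims& d = dims[i];
    if (type == L_DENSE) {
      const int w = wslot[i];
      const fmat& X = cache.dense_in[i];
      gW[w] = X * dZ.t();
      gb[w] = arma::sum(dZ, 1);
      dZ = Wts[w] * dZ;
      // relu of the *previous* dense layer is applied when we reach it; but
      // if the layer below is a dense with relu we mask using its cached
      // output; if below is conv-domain, unflatten first.
      bool below_dense = (i - 1 >= start) && layers(i - 1, 0) == L_DENSE;
      if (below_dense) {
        if (layers(i - 1, 3)) {
          const fmat& out_prev = cache.act[i - 1];
          dZ %= arma::conv_to<fmat>::from(out_prev > 0.0f);
        }
      } else if (i - 1 >= start) {
        // unflatten F x B -> (B*HW) x C
        const int HW = d.h_in * d.w_in, C = d.c_in;
        dA.set_size((arma::uword)B * HW, C);
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < C; ++c)
            std::memcpy(dA.colptr(c) + b * HW, dZ.colptr(b) + c * HW,
                        HW * sizeof(float));
        in_dense = false;
      }
    } else if (type == L_MAXPOOL) {
      const arma::umat& idx = cache.poolidx[i];
      fmat up((arma::uword)B * d.h_in * d.w_in, d.c_in, arma::fill::zeros);
      for (int c = 0; c < d.c_in; ++c) {
        const float* src = dA.colptr(c);
        const arma::uword* ix = idx.colptr(c);
        float* dst = up.colptr(c);
        const arma::uword n = (arma::uword)B * d.h_out * d.w_out;
        for (arma::uword j = 0; j < n; ++j) dst[ix[j]] += src[j];
      }
      dA = std::move(up);
    } else if (type == L_CONV) {
      const int w = wslot[i];
      // relu mask of this conv's own output
      const fmat& out = cache.act[i];
      dA %= arma::conv_to<fmat>::from(out > 0.0f);
      const fmat& col = cache.col[i];
      gW[w] = col.t() * dA;
      gb[w] = arma::sum(dA, 0).t();
      if (i - 1 >= start) {
        fmat dcol = dA * Wts[w].t();
        col2im(dcol, B, d.h_in, d.w_in, d.c_in, dA);
      }
    } else if (type == L_AVGPOOL) {
      break;  // stem carries no parameters
    }
  }
  (void)in_dense; (void)A0;
}

static void to_float_weights(const IntegerMatrix& layers, const List& weights,
                             std::vector<fmat>& Wts, std::vector<fvec>& bs,
                             std::vector<int>& wslot) {
  wslot.assign(layers.nrow(), -1);
  int slot = 0, li = 0;
  for (int i = 0; i < layers.nrow(); ++i) {
    int type = layers(i, 0);
    if (type == L_CONV || type == L_DENSE) {
      NumericMatrix Wm = weights[li++];
      NumericVector bv = weights[li++];
      fmat Wf(Wm.nrow(), Wm.ncol());
      for (int j = 0; j < Wm.ncol(); ++j)
        for (int r = 0; r < Wm.nrow(); ++r) Wf(r, j) = (float)Wm(r, j);
      fvec bf(bv.size());
      for (int r = 0; r < bv.size(); ++r) bf[r] = (float)bv[r];
      Wts.push_back(std::move(Wf));
      bs.push_back(std::move(bf));
      wslot[i] = slot++;
    }
  }
}

static List from_float_weights(const IntegerMatrix& layers,
                               const std::vector<fmat>& Wts, const std::vector<fvec>& bs) {
  List out;
  int slot = 0;
  for (int i = 0; i < layers.nrow(); ++i) {
    int type = layers(i, 0);
    if (type == L_CONV || type == L_DENSE) {
      const fmat& Wf = Wts[slot]; const fvec& bf = bs[slot];
      NumericMatrix Wm(Wf.n_rows, Wf.n_cols);
      for (arma::uword j = 0; j < Wf.n_cols; ++j)
        for (arma::uword r = 0; r < Wf.n_rows; ++r) Wm(r, j) = Wf(r, j);
      NumericVector bv(bf.n_elem);
      for (arma::uword r = 0; r < bf.n_elem; ++r) bv[r] = bf[r];
      out.push_back(Wm);
      out.push_back(bv);
      ++slot;
    }
  }
  return out;
}

static fmat dataset_to_float(const RawMatrix& X, const IntegerMatrix& layers,
                             int H, int W, int& h0, int& w0, int& start) {
  // X: (H*W) x n raw 0/1 masks
  const int n = X.ncol();
  fmat Xf(H * W, n);
  for (int s = 0; s < n; ++s)
    for (int p = 0; p < H * W; ++p)
      Xf(p, s) = (float)X(p, s);
  start = 0; h0 = H; w0 = W;
  if (layers(0, 0) == L_AVGPOOL) {
    int ky = layers(0, 1), kx = layers(0, 2);
    if (kx == 0) kx = ky;
    Xf = avgpool_stem(Xf, H, W, ky, kx);
    h0 = H / ky; w0 = W / kx; start = 1;
  }
  return Xf;
}

static inline double clamp_pt(double u, double eps) {
  if (u < eps) return eps;
  if (u > 1.0 - eps) return 1.0 - eps;
  return u;
}

// [[Rcpp::export]]
List cnn_train_cpp(IntegerMatrix layers, List weights, RawMatrix X,
                   int H, int W, IntegerVector y,
                   double lr, double momentum, int batch, int epochs,
                   double gamma, double alpha, int seed, bool augment_shift = false) {
  const int n = X.ncol();
  if (y.size() != n) stop("label/sample count mismatch");
  std::vector<LayerDims> dims = layer_dims(layers, H, W);
  std::vector<fmat> Wts; std::vector<fvec> bs; std::vector<int> wslot;
  to_float_weights(layers, weights, Wts, bs, wslot);
  int h0, w0, start;
  fmat Xf = dataset_to_float(X, layers, H, W, h0, w0, start);
  const int HW = h0 * w0;

  std::vector<fmat> vW(Wts.size());
  std::vector<fvec> vb(bs.size());
  for (size_t s = 0; s < Wts.size(); ++s) {
    vW[s].zeros(Wts[s].n_rows, Wts[s].n_cols);
    vb[s].zeros(bs[s].n_elem);
  }
  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector loss_trace(epochs), acc_trace(epochs);
  const double eps = 1e-7;
  std::vector<fmat> gW(Wts.size());
  std::vector<fvec> gb(bs.size());
  Cache cache;

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0; int correct = 0;
    for (int off = 0; off < n; off += batch) {
      const int B = std::min(batch, n - off);
      fmat A0(HW * B, 1);
      for (int b = 0; b < B; ++b) {
        const float* src = Xf.colptr(order[off + b]);
        float* dst = A0.colptr(0) + b * HW;
        if (augment_shift) {
          // random circular shift of the angular (column) axis: in polar
          // coordinates an in-plane rotation is exactly a column rotation
          const int s = (int)(rng() % (unsigned)w0);
          for (int x = 0; x < w0; ++x)
            std::memcpy(dst + x * h0, src + ((x + s) % w0) * h0,
                        h0 * sizeof(float));
        } else {
          std::memcpy(dst, src, HW * sizeof(float));
        }
      }
      fmat logits = forward(layers, dims, Wts, bs, wslot, A0, B, start, true, &cache);
      fmat dZ(1, B);
      for (int b = 0; b < B; ++b) {
        const int yb = y[order[off + b]];
        const double z = logits(0, b);
        const double p = 1.0 / (1.0 + std::exp(-z));
        const double u = clamp_pt(yb == 1 ? p : 1.0 - p, eps);
        loss_sum += -alpha * std::pow(1.0 - u, gamma) * std::log(u);
        if ((p >= 0.5 ? 1 : 0) == yb) ++correct;
        const double g = -alpha * (2 * yb - 1) *
          (std::pow(1.0 - u, gamma + 1.0) -
           gamma * u * std::log(u) * std::pow(1.0 - u, gamma));
        dZ(0, b) = (float)(g / B);
      }
      backward(layers, dims, Wts, wslot, cache, A0, B, start, dZ, gW, gb);
      for (size_t s = 0; s < Wts.size(); ++s) {
        vW[s] = (float)momentum * vW[s] + gW[s];
        vb[s] = (float)momentum * vb[s] + gb[s];
        Wts[s] -= (float)lr * vW[s];
        bs[s] -= (float)lr * vb[s];
      }
    }
    loss_trace[e] = loss_sum / n;
    acc_trace[e] = (double)correct / n;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = from_float_weights(layers, Wts, bs),
                      _["loss"] = loss_trace, _["train_accuracy"] = acc_trace);
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(IntegerMatrix layers, List weights, RawMatrix X,
                              int H, int W, int chunk = 64) {
  const int n = X.ncol();
  std::vector<LayerDims> dims = layer_dims(layers, H, W);
  std::vector<fmat> Wts; std::vector<fvec> bs; std::vector<int> wslot;
  to_float_weights(layers, weights, Wts, bs, wslot);
  int h0, w0, start;
  fmat Xf = dataset_to_float(X, layers, H, W, h0, w0, start);
  const int HW = h0 * w0;
  NumericVector probs(n);
  for (int off = 0; off < n; off += chunk) {
    const int B = std::min(chunk, n - off);
    fmat A0(HW * B, 1);
    for (int b = 0; b < B; ++b)
      std::memcpy(A0.colptr(0) + b * HW, Xf.colptr(off + b), HW * sizeof(float));
    fmat logits = forward(layers, dims, Wts, bs, wslot, A0, B, start, false, nullptr);
    for (int b = 0; b < B; ++b)
      probs[off + b] = 1.0 / (1.0 + std::exp(-(double)logits(0, b)));
  }
  return probs;
}
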