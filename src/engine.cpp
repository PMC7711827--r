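// Single-precision training engine for the LB-FCN light architecture family:
// depthwise separable convolutions (same padding, dilation), per-branch batch
// normalization, multi-scale concatenation, look-behind residual addition via
// pointwise projection, 2x2 max pooling, global average pooling and a 3-way
// softmax head.  Templated on the element type so the identical code path can
// be exercised in double precision by the finite-difference gradient tests.
//
// Activation layout: Mat<T> of shape (N*H*W, C); within a column the element
// for sample n at pixel (i, j) sits at index n*H*W + i*W + j.  Columns are
// contiguous, so per-channel spatial loops and per-channel BN reductions both
// stream memory linearly, and pointwise convolutions are plain GEMMs.

#include <RcppArmadillo.h>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct BranchSpec { int k; int d; };

struct Arch {
  int in_channels;
  int input_size;                    // square spatial input
  std::vector<std::vector<BranchSpec>> branches;  // per block
  std::vector<int> filters;          // per-branch filter count, per block
  std::vector<int> residual;         // 0/1 per block
  int n_classes;
};

Arch parse_arch(const List& a) {
  Arch arch;
  arch.in_channels = as<int>(a["channels"]);
  arch.input_size  = as<int>(a["input_size"]);
  arch.n_classes   = as<int>(a["n_classes"]);
  List blocks = a["blocks"];
  for (int b = 0; b < blocks.size(); ++b) {
    List blk = blocks[b];
    IntegerVector ks = blk["kernels"], ds = blk["dilations"];
    std::vector<BranchSpec> br;
    for (int j = 0; j < ks.size(); ++j) br.push_back({ks[j], ds[j]});
    arch.branches.push_back(br);
    arch.filters.push_back(as<int>(blk["filters"]));
    arch.residual.push_back(as<int>(blk["residual"]));
  }
  return arch;
}

// Per-block channel bookkeeping.
inline int block_out_channels(const Arch& a, int b) {
  return (int)a.branches[b].size() * a.filters[b];
}
inline int block_in_channels(const Arch& a, int b) {
  return b == 0 ? a.in_channels : block_out_channels(a, b - 1);
}

// Trainable parameter layout (order matters and is frozen):
// per block: [dw_1 | pw_1 | gamma_1 | beta_1 | dw_2 | ... | proj | gammaP | betaP]
// head: [dense W (C x classes) | dense bias].
// dw_j is (k*k*Cin), channel-major: weight(c, a, b) = w[c*k*k + a*k + b].
long n_params(const Arch& a) {
  long n = 0;
  int nb = (int)a.branches.size();
  for (int b = 0; b < nb; ++b) {
    int cin = block_in_channels(a, b), F = a.filters[b];
    for (const auto& br : a.branches[b])
      n += (long)br.k * br.k * cin + (long)cin * F + 2L * F;
    if (a.residual[b]) {
      int cout = block_out_channels(a, b);
      n += (long)cin * cout + 2L * cout;
    }
  }
  int ctop = block_out_channels(a, nb - 1);
  n += (long)ctop * a.n_classes + a.n_classes;
  return n;
}

// Non-trainable state: running mean + running var for every BN channel,
// ordered as the BN layers appear in the parameter layout.
long n_state(const Arch& a) {
  long n = 0;
  int nb = (int)a.branches.size();
  for (int b = 0; b < nb; ++b) {
    n += 2L * (long)a.branches[b].size() * a.filters[b];
    if (a.residual[b]) n += 2L * block_out_channels(a, b);
  }
  return n;
}

const double BN_EPS = 1e-3;
const double BN_MOMENTUM = 0.9;

// ---- depthwise convolution ------------------------------------------------

template <typename T>
void dw_forward(const arma::Mat<T>& X, arma::Mat<T>& Y, const T* w,
                int N, int H, int W, int k, int d) {
  const int h = (k - 1) / 2, HW = H * W;
  Y.zeros(X.n_rows, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const T* xc = X.colptr(c);
    T* yc = Y.colptr(c);
    const T* wc = w + (size_t)c * k * k;
    for (int n = 0; n < N; ++n) {
      const T* xn = xc + (size_t)n * HW;
      T* yn = yc + (size_t)n * HW;
      for (int a = 0; a < k; ++a) {
        int di = d * (a - h);
        for (int b = 0; b < k; ++b) {
          int dj = d * (b - h);
          T wv = wc[a * k + b];
          if (wv == T(0)) continue;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          for (int i = i0; i < i1; ++i) {
            const T* xrow = xn + (size_t)(i + di) * W + dj;
            T* yrow = yn + (size_t)i * W;
            for (int j = j0; j < j1; ++j) yrow[j] += wv * xrow[j];
          }
        }
      }
    }
  }
}

template <typename T>
void dw_backward(const arma::Mat<T>& X, const arma::Mat<T>& dY,
                 arma::Mat<T>& dX, T* dw, const T* w,
                 int N, int H, int W, int k, int d) {
  const int h = (k - 1) / 2, HW = H * W;
  dX.zeros(X.n_rows, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const T* xc = X.colptr(c);
    const T* gc = dY.colptr(c);
    T* dxc = dX.colptr(c);
    const T* wc = w + (size_t)c * k * k;
    T* dwc = dw + (size_t)c * k * k;
    for (int n = 0; n < N; ++n) {
      const T* xn = xc + (size_t)n * HW;
      const T* gn = gc + (size_t)n * HW;
      T* dxn = dxc + (size_t)n * HW;
      for (int a = 0; a < k; ++a) {
        int di = d * (a - h);
        for (int b = 0; b < k; ++b) {
          int dj = d * (b - h);
          T wv = wc[a * k + b];
          T acc = 0;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          for (int i = i0; i < i1; ++i) {
            const T* xrow = xn + (size_t)(i + di) * W + dj;
            T* dxrow = dxn + (size_t)(i + di) * W + dj;
            const T* grow = gn + (size_t)i * W;
            for (int j = j0; j < j1; ++j) {
              acc += grow[j] * xrow[j];
              dxrow[j] += grow[j] * wv;
            }
          }
          dwc[a * k + b] += acc;
        }
      }
    }
  }
}

// ---- batch normalization --------------------------------------------------

template <typename T>
struct BNCache {
  arma::Row<T> mu, invstd;
  arma::Mat<T> xhat;
};

template <typename T>
void bn_forward_train(arma::Mat<T>& X, const T* gamma, const T* beta,
                      double* rmean, double* rvar, BNCache<T>& cache,
                      double momentum = BN_MOMENTUM) {
  const double M = (double)X.n_rows;
  cache.mu.set_size(X.n_cols);
  cache.invstd.set_size(X.n_cols);
  cache.xhat.set_size(X.n_rows, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    T* xc = X.colptr(c);
    double s = 0, s2 = 0;
    for (arma::uword i = 0; i < X.n_rows; ++i) { s += xc[i]; }
    double mu = s / M;
    for (arma::uword i = 0; i < X.n_rows; ++i) { double e = xc[i] - mu; s2 += e * e; }
    double var = s2 / M;
    double invstd = 1.0 / std::sqrt(var + BN_EPS);
    rmean[c] = momentum * rmean[c] + (1 - momentum) * mu;
    rvar[c]  = momentum * rvar[c]  + (1 - momentum) * var;
    cache.mu[c] = (T)mu; cache.invstd[c] = (T)invstd;
    T* xh = cache.xhat.colptr(c);
    T g = gamma[c], b = beta[c];
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      xh[i] = (T)((xc[i] - mu) * invstd);
      xc[i] = g * xh[i] + b;
    }
  }
}

template <typename T>
void bn_forward_eval(arma::Mat<T>& X, const T* gamma, const T* beta,
                     const double* rmean, const double* rvar) {
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    T* xc = X.colptr(c);
    double invstd = 1.0 / std::sqrt(rvar[c] + BN_EPS);
    double mu = rmean[c];
    T g = gamma[c], b = beta[c];
    for (arma::uword i = 0; i < X.n_rows; ++i)
      xc[i] = (T)(g * ((xc[i] - mu) * invstd) + b);
  }
}

template <typename T>
void bn_backward(arma::Mat<T>& dY, const BNCache<T>& cache, const T* gamma,
                 T* dgamma, T* dbeta) {
  const double M = (double)dY.n_rows;
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    T* dy = dY.colptr(c);
    const T* xh = cache.xhat.colptr(c);
    double sdy = 0, sdyxh = 0;
    for (arma::uword i = 0; i < dY.n_rows; ++i) { sdy += dy[i]; sdyxh += dy[i] * xh[i]; }
    dgamma[c] += (T)sdyxh;
    dbeta[c]  += (T)sdy;
    double g = gamma[c], invstd = cache.invstd[c];
    for (arma::uword i = 0; i < dY.n_rows; ++i)
      dy[i] = (T)(g * invstd * (dy[i] - sdy / M - xh[i] * sdyxh / M));
  }
}

// ---- pooling --------------------------------------------------------------

template <typename T>
void maxpool_forward(const arma::Mat<T>& X, arma::Mat<T>& Y, arma::umat& amax,
                     int N, int H, int W) {
  int H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  Y.set_size((size_t)N * HW2, X.n_cols);
  amax.set_size((size_t)N * HW2, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const T* xc = X.colptr(c);
    T* yc = Y.colptr(c);
    arma::uword* ac = amax.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int i = 0; i < H2; ++i) {
        for (int j = 0; j < W2; ++j) {
          size_t base = (size_t)n * HW + (size_t)(2 * i) * W + 2 * j;
          size_t cand[4] = {base, base + 1, base + W, base + W + 1};
          size_t best = cand[0];
          for (int q = 1; q < 4; ++q) if (xc[cand[q]] > xc[best]) best = cand[q];
          size_t out = (size_t)n * HW2 + (size_t)i * W2 + j;
          yc[out] = xc[best];
          ac[out] = best;
        }
      }
    }
  }
}

template <typename T>
void maxpool_backward(const arma::Mat<T>& dY, const arma::umat& amax,
                      arma::Mat<T>& dX, size_t in_rows) {
  dX.zeros(in_rows, dY.n_cols);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const T* dy = dY.colptr(c);
    const arma::uword* ac = amax.colptr(c);
    T* dx = dX.colptr(c);
    for (arma::uword r = 0; r < dY.n_rows; ++r) dx[ac[r]] += dy[r];
  }
}

// ---- forward/backward over the whole network ------------------------------

template <typename T>
struct BlockCache {
  arma::Mat<T> x_in;                       // block input
  std::vector<arma::Mat<T>> dw_out;        // depthwise outputs per branch
  std::vector<BNCache<T>> bn;              // per-branch BN caches
  BNCache<T> bn_proj;
  arma::Mat<T> merged;                     // post-(concat[+residual]) pre-pool
  arma::umat amax;
  int H;                                   // spatial size at block input
};

struct Offsets {
  // per block, per branch: dw, pw, gamma, beta; then proj, gammaP, betaP
  std::vector<std::vector<size_t>> dw, pw, ga, be;
  std::vector<size_t> proj, gaP, beP;
  size_t dense, bias;
  // state offsets per BN (mean; var follows immediately after mean block)
  std::vector<std::vector<size_t>> st;     // per block, per branch
  std::vector<size_t> stP;
};

Offsets layout(const Arch& a) {
  Offsets o;
  size_t p = 0, s = 0;
  int nb = (int)a.branches.size();
  o.dw.resize(nb); o.pw.resize(nb); o.ga.resize(nb); o.be.resize(nb);
  o.proj.resize(nb); o.gaP.resize(nb); o.beP.resize(nb);
  o.st.resize(nb); o.stP.resize(nb);
  for (int b = 0; b < nb; ++b) {
    int cin = block_in_channels(a, b), F = a.filters[b];
    for (size_t j = 0; j < a.branches[b].size(); ++j) {
      int k = a.branches[b][j].k;
      o.dw[b].push_back(p); p += (size_t)k * k * cin;
      o.pw[b].push_back(p); p += (size_t)cin * F;
      o.ga[b].push_back(p); p += F;
      o.be[b].push_back(p); p += F;
      o.st[b].push_back(s); s += 2 * (size_t)F;
    }
    if (a.residual[b]) {
      int cout = block_out_channels(a, b);
      o.proj[b] = p; p += (size_t)cin * cout;
      o.gaP[b] = p; p += cout;
      o.beP[b] = p; p += cout;
      o.stP[b] = s; s += 2 * (size_t)cout;
    }
  }
  int ctop = block_out_channels(a, nb - 1);
  o.dense = p; p += (size_t)ctop * a.n_classes;
  o.bias = p;
  return o;
}

// Forward pass; when training, caches are filled and BN uses batch statistics.
template <typename T>
arma::Mat<T> net_forward(const Arch& a, const Offsets& o, const T* w,
                         double* st, const arma::Mat<T>& X0, int N,
                         bool training, std::vector<BlockCache<T>>* caches,
                         arma::Mat<T>* gap_out, double bn_mom = BN_MOMENTUM) {
  int nb = (int)a.branches.size();
  arma::Mat<T> X = X0;
  int H = a.input_size, W = a.input_size;
  for (int b = 0; b < nb; ++b) {
    int cin = block_in_channels(a, b), F = a.filters[b];
    int nbr = (int)a.branches[b].size();
    int cout = nbr * F;
    BlockCache<T>* C = caches ? &((*caches)[b]) : nullptr;
    if (C) { C->x_in = X; C->H = H; C->dw_out.resize(nbr); C->bn.resize(nbr); }
    arma::Mat<T> merged(X.n_rows, cout);
    for (int j = 0; j < nbr; ++j) {
      int k = a.branches[b][j].k, d = a.branches[b][j].d;
      arma::Mat<T> Ydw;
      dw_forward(X, Ydw, w + o.dw[b][j], N, H, W, k, d);
      arma::Mat<T> Z = Ydw * arma::Mat<T>(const_cast<T*>(w + o.pw[b][j]), cin, F, false, true);
      if (C) C->dw_out[j] = std::move(Ydw);
      double* rm = st + o.st[b][j];
      if (training) {
        bn_forward_train(Z, w + o.ga[b][j], w + o.be[b][j], rm, rm + F, C->bn[j], bn_mom);
      } else {
        bn_forward_eval(Z, w + o.ga[b][j], w + o.be[b][j], rm, rm + F);
      }
      Z.for_each([](T& v) { if (v < T(0)) v = T(0); });   // ReLU
      merged.cols((size_t)j * F, (size_t)(j + 1) * F - 1) = Z;
    }
    if (a.residual[b]) {
      arma::Mat<T> R = X * arma::Mat<T>(const_cast<T*>(w + o.proj[b]), cin, cout, false, true);
      double* rm = st + o.stP[b];
      if (training) {
        bn_forward_train(R, w + o.gaP[b], w + o.beP[b], rm, rm + cout, C->bn_proj, bn_mom);
      } else {
        bn_forward_eval(R, w + o.gaP[b], w + o.beP[b], rm, rm + cout);
      }
      merged += R;
    }
    if (C) C->merged = merged;
    arma::Mat<T> pooled;
    arma::umat amax;
    maxpool_forward(merged, pooled, amax, N, H, W);
    if (C) C->amax = std::move(amax);
    X = std::move(pooled);
    H /= 2; W /= 2;
  }
  // global average pooling: (N*HW, C) -> (N, C)
  int ctop = block_out_channels(a, nb - 1);
  int HW = H * W;
  arma::Mat<T> G(N, ctop);
  for (int c = 0; c < ctop; ++c) {
    const T* xc = X.colptr(c);
    for (int n = 0; n < N; ++n) {
      T s = 0;
      const T* xn = xc + (size_t)n * HW;
      for (int q = 0; q < HW; ++q) s += xn[q];
      G(n, c) = s / (T)HW;
    }
  }
  if (gap_out) *gap_out = G;
  arma::Mat<T> logits = G * arma::Mat<T>(const_cast<T*>(w + o.dense), ctop, a.n_classes, false, true);
  logits.each_row() += arma::Row<T>(const_cast<T*>(w + o.bias), a.n_classes, false, true);
  // softmax
  for (int n = 0; n < N; ++n) {
    T m = logits.row(n).max();
    double s = 0;
    for (int c = 0; c < a.n_classes; ++c) { logits(n, c) = std::exp(logits(n, c) - m); s += logits(n, c); }
    for (int c = 0; c < a.n_classes; ++c) logits(n, c) = (T)(logits(n, c) / s);
  }
  return logits;   // probabilities
}

// Backward pass from softmax cross-entropy; fills grad (same layout as w).
// Returns mean cross-entropy loss.
template <typename T>
double net_loss_grad(const Arch& a, const Offsets& o, const T* w, double* st,
                     const arma::Mat<T>& X0, const IntegerVector& y, int N,
                     T* grad) {
  int nb = (int)a.branches.size();
  std::vector<BlockCache<T>> caches(nb);
  arma::Mat<T> G;
  arma::Mat<T> P = net_forward<T>(a, o, w, st, X0, N, true, &caches, &G);
  double loss = 0;
  arma::Mat<T> dlog = P;
  for (int n = 0; n < N; ++n) {
    double p = std::max((double)P(n, y[n]), 1e-12);
    loss -= std::log(p);
    dlog(n, y[n]) -= T(1);
  }
  loss /= N;
  dlog /= (T)N;

  int ctop = block_out_channels(a, nb - 1);
  // dense
  arma::Mat<T> Wd(const_cast<T*>(w + o.dense), ctop, a.n_classes, false, true);
  arma::Mat<T> dWd = G.t() * dlog;
  std::copy(dWd.begin(), dWd.end(), grad + o.dense);
  arma::Row<T> db = arma::sum(dlog, 0);
  std::copy(db.begin(), db.end(), grad + o.bias);
  arma::Mat<T> dG = dlog * Wd.t();

  // un-GAP
  int Hend = a.input_size >> nb, HW = Hend * Hend;
  arma::Mat<T> dX((size_t)N * HW, ctop);
  for (int c = 0; c < ctop; ++c) {
    T* dxc = dX.colptr(c);
    for (int n = 0; n < N; ++n) {
      T v = dG(n, c) / (T)HW;
      T* dxn = dxc + (size_t)n * HW;
      for (int q = 0; q < HW; ++q) dxn[q] = v;
    }
  }

  for (int b = nb - 1; b >= 0; --b) {
    BlockCache<T>& C = caches[b];
    int cin = block_in_channels(a, b), F = a.filters[b];
    int nbr = (int)a.branches[b].size(), cout = nbr * F;
    int H = C.H, W = C.H;
    arma::Mat<T> dMerged;
    maxpool_backward(dX, C.amax, dMerged, C.merged.n_rows);
    arma::Mat<T> dXin(C.x_in.n_rows, cin, arma::fill::zeros);
    if (a.residual[b]) {
      arma::Mat<T> dR = dMerged;   // residual add passes gradient through
      bn_backward(dR, C.bn_proj, w + o.gaP[b], grad + o.gaP[b], grad + o.beP[b]);
      arma::Mat<T> Wp(const_cast<T*>(w + o.proj[b]), cin, cout, false, true);
      arma::Mat<T> dWp = C.x_in.t() * dR;
      T* g = grad + o.proj[b];
      for (size_t q = 0; q < dWp.n_elem; ++q) g[q] += dWp[q];
      dXin += dR * Wp.t();
    }
    for (int j = 0; j < nbr; ++j) {
      int k = a.branches[b][j].k, d = a.branches[b][j].d;
      arma::Mat<T> dZ = dMerged.cols((size_t)j * F, (size_t)(j + 1) * F - 1);
      // ReLU mask: recompute from BN-affine output sign via xhat
      const T* ga = w + o.ga[b][j];
      const T* be = w + o.be[b][j];
      const arma::Mat<T>& xh = C.bn[j].xhat;
      for (int f = 0; f < F; ++f) {
        T* dz = dZ.colptr(f);
        const T* x = xh.colptr(f);
        T g = ga[f], bb = be[f];
        for (arma::uword r = 0; r < dZ.n_rows; ++r)
          if (g * x[r] + bb <= T(0)) dz[r] = T(0);
      }
      bn_backward(dZ, C.bn[j], ga, grad + o.ga[b][j], grad + o.be[b][j]);
      arma::Mat<T> Wpw(const_cast<T*>(w + o.pw[b][j]), cin, F, false, true);
      arma::Mat<T> dWpw = C.dw_out[j].t() * dZ;
      T* g = grad + o.pw[b][j];
      for (size_t q = 0; q < dWpw.n_elem; ++q) g[q] += dWpw[q];
      arma::Mat<T> dYdw = dZ * Wpw.t();
      arma::Mat<T> dXbr;
      dw_backward(C.x_in, dYdw, dXbr, grad + o.dw[b][j], w + o.dw[b][j], N, H, W, k, d);
      dXin += dXbr;
    }
    dX = std::move(dXin);
  }
  return loss;
}

// ---- initialization -------------------------------------------------------

template <typename T>
void init_weights(const Arch& a, const Offsets& o, T* w, std::mt19937& rng) {
  std::normal_distribution<double> nd(0.0, 1.0);
  std::uniform_real_distribution<double> ud(-1.0, 1.0);
  int nb = (int)a.branches.size();
  for (int b = 0; b < nb; ++b) {
    int cin = block_in_channels(a, b), F = a.filters[b];
    for (size_t j = 0; j < a.branches[b].size(); ++j) {
      int k = a.branches[b][j].k;
      double sd_dw = std::sqrt(2.0 / (k * k));          // He, per-channel fan-in
      size_t ndw = (size_t)k * k * cin;
      for (size_t q = 0; q < ndw; ++q) w[o.dw[b][j] + q] = (T)(sd_dw * nd(rng));
      double sd_pw = std::sqrt(2.0 / cin);
      size_t npw = (size_t)cin * F;
      for (size_t q = 0; q < npw; ++q) w[o.pw[b][j] + q] = (T)(sd_pw * nd(rng));
      for (int f = 0; f < F; ++f) { w[o.ga[b][j] + f] = T(1); w[o.be[b][j] + f] = T(0); }
    }
    if (a.residual[b]) {
      int cout = block_out_channels(a, b);
      double sd_p = std::sqrt(2.0 / cin);
      size_t np = (size_t)cin * cout;
      for (size_t q = 0; q < np; ++q) w[o.proj[b] + q] = (T)(sd_p * nd(rng));
      for (int f = 0; f < cout; ++f) { w[o.gaP[b] + f] = T(1); w[o.beP[b] + f] = T(0); }
    }
  }
  int ctop = block_out_channels(a, nb - 1);
  double lim = std::sqrt(6.0 / (ctop + a.n_classes));   // Glorot uniform
  for (size_t q = 0; q < (size_t)ctop * a.n_classes; ++q) w[o.dense + q] = (T)(lim * ud(rng));
  for (int c = 0; c < a.n_classes; ++c) w[o.bias + c] = T(0);
}

// ---- geometric transforms (shared with the preprocess module) -------------

// Inverse-mapped bilinear rotation about the image center combined with an
// isotropic zoom; zero fill outside the source support.
template <typename T>
void rotate_zoom(const T* src, T* dst, int H, int W, double angle_deg, double zoom) {
  double th = angle_deg * M_PI / 180.0;
  double ca = std::cos(th) / zoom, sa = std::sin(th) / zoom;
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double dy = i - cy, dx = j - cx;
      double sy = cy + ca * dy - sa * dx;
      double sx = cx + sa * dy + ca * dx;
      T v = 0;
      if (sy >= 0 && sy <= H - 1 && sx >= 0 && sx <= W - 1) {
        int i0 = (int)std::floor(sy), j0 = (int)std::floor(sx);
        int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        double fy = sy - i0, fx = sx - j0;
        v = (T)((1 - fy) * ((1 - fx) * src[(size_t)i0 * W + j0] + fx * src[(size_t)i0 * W + j1]) +
                fy       * ((1 - fx) * src[(size_t)i1 * W + j0] + fx * src[(size_t)i1 * W + j1]));
      }
      dst[(size_t)i * W + j] = v;
    }
  }
}

}  // namespace

// ---- R interface ----------------------------------------------------------

// [[Rcpp::export]]
double cpp_net_nparams(List arch) {
  return (double)n_params(parse_arch(arch));
}

// [[Rcpp::export]]
double cpp_net_nstate(List arch) {
  return (double)n_state(parse_arch(arch));
}

// [[Rcpp::export]]
NumericVector cpp_net_init(List arch, int seed) {
  Arch a = parse_arch(arch);
  Offsets o = layout(a);
  std::vector<double> w(n_params(a));
  std::mt19937 rng((unsigned)seed);
  init_weights<double>(a, o, w.data(), rng);
  return NumericVector(w.begin(), w.end());
}

// Fresh BN state: running mean 0, running var 1.
// [[Rcpp::export]]
NumericVector cpp_net_init_state(List arch) {
  Arch a = parse_arch(arch);
  long ns = n_state(a);
  NumericVector st(ns);
  // layout is (mean block, var block) pairs; set var entries to 1
  Offsets o = layout(a);
  std::fill(st.begin(), st.end(), 0.0);
  int nb = (int)a.branches.size();
  for (int b = 0; b < nb; ++b) {
    int F = a.filters[b];
    for (size_t j = 0; j < a.branches[b].size(); ++j)
      for (int f = 0; f < F; ++f) st[o.st[b][j] + F + f] = 1.0;
    if (a.residual[b]) {
      int cout = block_out_channels(a, b);
      for (int f = 0; f < cout; ++f) st[o.stP[b] + cout + f] = 1.0;
    }
  }
  return st;
}

// Convert an R array (N, H, W, C) into the engine layout (N*H*W rows, C cols).
template <typename T>
static arma::Mat<T> ingest(const NumericVector& X) {
  IntegerVector dim = X.attr("dim");
  int N = dim[0], H = dim[1], W = dim[2], C = dim[3];
  arma::Mat<T> M((size_t)N * H * W, C);
  const double* x = X.begin();
  for (int c = 0; c < C; ++c) {
    T* mc = M.colptr(c);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double* src = x + (size_t)N * (i + (size_t)H * (j + (size_t)W * c));
        for (int n = 0; n < N; ++n)
          mc[(size_t)n * H * W + (size_t)i * W + j] = (T)src[n];
      }
  }
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_net_predict(List arch, NumericVector w, NumericVector state,
                              NumericVector X) {
  Arch a = parse_arch(arch);
  Offsets o = layout(a);
  IntegerVector dim = X.attr("dim");
  int N = dim[0];
  arma::fmat Xm = ingest<float>(X);
  std::vector<float> wf(w.begin(), w.end());
  std::vector<double> st(state.begin(), state.end());
  arma::fmat P = net_forward<float>(a, o, wf.data(), st.data(), Xm, N, false, nullptr, nullptr);
  NumericMatrix out(N, a.n_classes);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < a.n_classes; ++c) out(n, c) = P(n, c);
  return out;
}

// Double-precision loss + gradient in training mode (batch statistics); used
// by the finite-difference gradient tests and small-scale diagnostics.
// [[Rcpp::export]]
List cpp_net_loss_grad(List arch, NumericVector w, NumericVector state,
                       NumericVector X, IntegerVector y) {
  Arch a = parse_arch(arch);
  Offsets o = layout(a);
  IntegerVector dim = X.attr("dim");
  int N = dim[0];
  arma::mat Xm = ingest<double>(X);
  std::vector<double> wd(w.begin(), w.end());
  std::vector<double> st(state.begin(), state.end());
  std::vector<double> grad(w.size(), 0.0);
  double loss = net_loss_grad<double>(a, o, wd.data(), st.data(), Xm, y, N, grad.data());
  return List::create(_["loss"] = loss,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// Full training loop: epochs x minibatches with Adam, optional per-image
// rotation/zoom augmentation, deterministic under (seed).
// [[Rcpp::export]]
List cpp_net_train(List arch, NumericVector w0, NumericVector state0,
                   NumericVector X, IntegerVector y,
                   int epochs, int batch_size,
                   double lr, double beta1, double beta2, double adam_eps,
                   int seed, bool augment, double rot_max_deg,
                   double zoom_min, double zoom_max) {
  Arch a = parse_arch(arch);
  Offsets o = layout(a);
  IntegerVector dim = X.attr("dim");
  int N = dim[0], H = dim[1], W = dim[2], C = dim[3];
  if (H != a.input_size || W != a.input_size || C != a.in_channels)
    stop("input array does not match the architecture input shape");
  if (N < 1) stop("empty training set");
  arma::fmat Xall = ingest<float>(X);
  size_t P = w0.size();
  std::vector<float> w(w0.begin(), w0.end());
  std::vector<double> st(state0.begin(), state0.end());
  std::vector<float> grad(P), m(P, 0.0f), v(P, 0.0f);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> uang(-rot_max_deg, rot_max_deg);
  std::uniform_real_distribution<double> uzoom(zoom_min, zoom_max);
  std::vector<int> idx(N);
  for (int n = 0; n < N; ++n) idx[n] = n;
  NumericVector trace(epochs);
  long t = 0;
  const int HW = H * W;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double esum = 0;
    int nbatch = 0;
    for (int s = 0; s < N; s += batch_size) {
      int nb = std::min(batch_size, N - s);
      arma::fmat Xb((size_t)nb * HW, C);
      IntegerVector yb(nb);
      std::vector<float> tmp(HW);
      for (int q = 0; q < nb; ++q) {
        int n = idx[s + q];
        yb[q] = y[n];
        double ang = 0, zm = 1;
        if (augment) { ang = uang(rng); zm = uzoom(rng); }
        for (int c = 0; c < C; ++c) {
          const float* src = Xall.colptr(c) + (size_t)n * HW;
          float* dst = Xb.colptr(c) + (size_t)q * HW;
          if (augment && (ang != 0 || zm != 1)) {
            rotate_zoom<float>(src, tmp.data(), H, W, ang, zm);
            std::copy(tmp.begin(), tmp.end(), dst);
          } else {
            std::copy(src, src + HW, dst);
          }
        }
      }
      std::fill(grad.begin(), grad.end(), 0.0f);
      double loss = net_loss_grad<float>(a, o, w.data(), st.data(), Xb, yb, nb, grad.data());
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", e + 1);
      esum += loss;
      ++nbatch;
      ++t;
      double bc1 = 1.0 - std::pow(beta1, (double)t);
      double bc2 = 1.0 - std::pow(beta2, (double)t);
      for (size_t q = 0; q < P; ++q) {
        m[q] = (float)(beta1 * m[q] + (1 - beta1) * grad[q]);
        v[q] = (float)(beta2 * v[q] + (1 - beta2) * grad[q] * grad[q]);
        w[q] -= (float)(lr * (m[q] / bc1) / (std::sqrt(v[q] / bc2) + adam_eps));
      }
    }
    trace[e] = esum / std::max(nbatch, 1);
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["state"] = NumericVector(st.begin(), st.end()),
                      _["loss_trace"] = trace);
}

// Batch-norm calibration: re-estimates every BN layer's running mean and
// variance over clean (un-augmented) training images so inference
// statistics match the data the network is evaluated on.  Batches are
// shuffled (the caller's data is typically grouped by class, and
// single-class batches would skew every layer's statistics), and the
// total variance is aggregated exactly as E[batch var] + Var[batch mean]
// rather than by averaging batch variances.
// [[Rcpp::export]]
NumericVector cpp_net_calibrate(List arch, NumericVector w, NumericVector state,
                                NumericVector X, int batch_size) {
  Arch a = parse_arch(arch);
  Offsets o = layout(a);
  IntegerVector dim = X.attr("dim");
  int N = dim[0], H = dim[1], W = dim[2];
  arma::fmat Xall = ingest<float>(X);
  std::vector<float> wf(w.begin(), w.end());
  std::vector<double> st(state.begin(), state.end());
  const int HW = H * W;
  long nchan = n_state(a) / 2;
  std::vector<double> s_mu(nchan, 0.0), s_var(nchan, 0.0), s_mu2(nchan, 0.0);
  std::vector<int> idx(N);
  for (int n = 0; n < N; ++n) idx[n] = n;
  std::mt19937 rng(760213u);           // fixed: calibration is deterministic
  int nb = 0;
  for (int pass = 0; pass < 2; ++pass) {
  std::shuffle(idx.begin(), idx.end(), rng);
  for (int s0 = 0; s0 < N; s0 += batch_size) {
    int nbt = std::min(batch_size, N - s0);
    if (nbt < 2) break;                // a 1-image tail batch has no variance
    arma::fmat Xb((size_t)nbt * HW, Xall.n_cols);
    for (arma::uword c = 0; c < Xall.n_cols; ++c)
      for (int q = 0; q < nbt; ++q)
        std::copy(Xall.colptr(c) + (size_t)idx[s0 + q] * HW,
                  Xall.colptr(c) + (size_t)(idx[s0 + q] + 1) * HW,
                  Xb.colptr(c) + (size_t)q * HW);
    std::vector<double> stb = st;      // scratch; batch stats land in acc
    std::vector<BlockCache<float>> caches(a.branches.size());
    net_forward<float>(a, o, wf.data(), stb.data(), Xb, nbt, true, &caches, nullptr, 0.0);
    // momentum 0: stb now holds this batch's statistics exactly;
    // walk the BN layers through the state layout and accumulate moments
    int nblk = (int)a.branches.size();
    for (int b = 0; b < nblk; ++b) {
      int F = a.filters[b];
      for (size_t j = 0; j < a.branches[b].size(); ++j) {
        size_t off = o.st[b][j];
        for (int f = 0; f < F; ++f) {
          double mu = stb[off + f], var = stb[off + F + f];
          long cid = (long)off / 2 + f;
          s_mu[cid] += mu; s_var[cid] += var; s_mu2[cid] += mu * mu;
        }
      }
      if (a.residual[b]) {
        int cout = block_out_channels(a, b);
        size_t off = o.stP[b];
        for (int f = 0; f < cout; ++f) {
          double mu = stb[off + f], var = stb[off + cout + f];
          long cid = (long)off / 2 + f;
          s_mu[cid] += mu; s_var[cid] += var; s_mu2[cid] += mu * mu;
        }
      }
    }
    ++nb;
  }
  }
  if (nb > 0) {
    int nblk = (int)a.branches.size();
    for (int b = 0; b < nblk; ++b) {
      int F = a.filters[b];
      for (size_t j = 0; j < a.branches[b].size(); ++j) {
        size_t off = o.st[b][j];
        for (int f = 0; f < F; ++f) {
          long cid = (long)off / 2 + f;
          double m = s_mu[cid] / nb;
          st[off + f] = m;
          st[off + F + f] = s_var[cid] / nb + s_mu2[cid] / nb - m * m;
        }
      }
      if (a.residual[b]) {
        int cout = block_out_channels(a, b);
        size_t off = o.stP[b];
        for (int f = 0; f < cout; ++f) {
          long cid = (long)off / 2 + f;
          double m = s_mu[cid] / nb;
          st[off + f] = m;
          st[off + cout + f] = s_var[cid] / nb + s_mu2[cid] / nb - m * m;
        }
      }
    }
  }
  return NumericVector(st.begin(), st.end());
}

// ---- standalone image ops for the preprocess module -----------------------

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  if (H == out_h && W == out_w) { out = clone(img); return out; }
  // align-corners-false convention (pixel centers at half-integers)
  double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int i = 0; i < out_h; ++i) {
    double fy = (i + 0.5) * sy - 0.5;
    int i0 = (int)std::floor(fy);
    double wy = fy - i0;
    int ia = std::min(std::max(i0, 0), H - 1), ib = std::min(std::max(i0 + 1, 0), H - 1);
    for (int j = 0; j < out_w; ++j) {
      double fx = (j + 0.5) * sx - 0.5;
      int j0 = (int)std::floor(fx);
      double wx = fx - j0;
      int ja = std::min(std::max(j0, 0), W - 1), jb = std::min(std::max(j0 + 1, 0), W - 1);
      out(i, j) = (1 - wy) * ((1 - wx) * img(ia, ja) + wx * img(ia, jb)) +
                  wy       * ((1 - wx) * img(ib, ja) + wx * img(ib, jb));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_zoom(NumericMatrix img, double angle_deg, double zoom) {
  int H = img.nrow(), W = img.ncol();
  // matrix is column-major; transform expects row-major — work on transposes
  std::vector<double> src((size_t)H * W), dst((size_t)H * W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) src[(size_t)i * W + j] = img(i, j);
  rotate_zoom<double>(src.data(), dst.data(), H, W, angle_deg, zoom);
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) out(i, j) = dst[(size_t)i * W + j];
  return out;
}
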