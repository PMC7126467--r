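// Residual network for beta-beta pairing prediction.
//
// Forward pass, masked row/column/instance normalizations and full
// reverse-mode gradients are implemented here; the training loop (Adam,
// fold splitting, early stopping) lives in R. Feature tensors are L x L
// x C arrays (arma::cube with channels as slices); parameters travel as
// one flat vector whose layout is defined in R/pairnet.R and mirrored
// in ParamView below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Cfg {
  int Cin, C, B;
  bool use_rncn;
  double slope, eps;
};

Cfg parse_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.Cin = Rcpp::as<int>(cfg["n_input"]);
  c.C = Rcpp::as<int>(cfg["n_channels"]);
  c.B = Rcpp::as<int>(cfg["n_blocks"]);
  c.use_rncn = Rcpp::as<bool>(cfg["use_rncn"]);
  c.slope = Rcpp::as<double>(cfg["leaky_slope"]);
  c.eps = Rcpp::as<double>(cfg["epsilon"]);
  return c;
}

// Flat parameter vector layout (offsets in doubles):
//   Win (Cin x C), bin (C),
//   per block: g1(C), be1(C), W1(3x3xCxC), b1(C), g2(C), be2(C),
//              W2(3x3xCxC), b2(C),
//   wout (C), bout (1).
// Conv weight index: (di+1) + 3*(dj+1) + 9*cin + 9*C*cout.
struct ParamView {
  int Cin, C, B;
  size_t conv_sz, block_sz, total;
  ParamView(int Cin_, int C_, int B_) : Cin(Cin_), C(C_), B(B_) {
    conv_sz = size_t(9) * C * C;
    block_sz = 2 * conv_sz + 6 * size_t(C);
    total = size_t(Cin) * C + C + B * block_sz + C + 1;
  }
  size_t win() const { return 0; }
  size_t bin() const { return size_t(Cin) * C; }
  size_t block(int b) const { return bin() + C + b * block_sz; }
  size_t g1(int b) const { return block(b); }
  size_t be1(int b) const { return block(b) + C; }
  size_t W1(int b) const { return block(b) + 2 * size_t(C); }
  size_t b1(int b) const { return W1(b) + conv_sz; }
  size_t g2(int b) const { return b1(b) + C; }
  size_t be2(int b) const { return b1(b) + 2 * size_t(C); }
  size_t W2(int b) const { return be2(b) + C; }
  size_t b2(int b) const { return W2(b) + conv_sz; }
  size_t wout() const { return block(B); }
  size_t bout() const { return wout() + C; }
};

// ---------------------------------------------------------------------
// masked normalization cores
// axis 0: statistics over j for each (row i, channel c)
// axis 1: statistics over i for each (column j, channel c)
// axis 2: statistics over all masked pixels for each channel c
// Groups with fewer than 2 masked entries pass through unchanged.

struct NormCache {
  cube xhat;
  mat sigma;   // per group x channel (axis 2: 1 x C)
  mat s;       // sigma + eps
  uvec nvalid; // per group (axis 2: length 1)
  int axis;
};

void norm_forward(const cube& x, const umat& mask, double eps, int axis,
                  NormCache& nc) {
  const int L = x.n_rows, C = x.n_slices;
  nc.axis = axis;
  nc.xhat.set_size(L, L, C);
  if (axis == 2) {
    nc.nvalid.set_size(1);
    nc.sigma.set_size(1, C);
    nc.s.set_size(1, C);
    uword n = accu(mask);
    nc.nvalid(0) = n;
    for (int c = 0; c < C; ++c) {
      const mat& xc = x.slice(c);
      if (n < 2) { nc.xhat.slice(c) = xc; continue; }
      double mu = 0;
      for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i)
          if (mask(i, j)) mu += xc(i, j);
      mu /= n;
      double var = 0;
      for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i)
          if (mask(i, j)) { double d = xc(i, j) - mu; var += d * d; }
      var /= n;
      double sg = std::sqrt(var), s = sg + eps;
      nc.sigma(0, c) = sg;
      nc.s(0, c) = s;
      nc.xhat.slice(c) = (xc - mu) / s;
    }
    return;
  }
  // axis 0 or 1
  nc.nvalid.set_size(L);
  nc.sigma.set_size(L, C);
  nc.s.set_size(L, C);
  for (int g = 0; g < L; ++g) {
    uword n = 0;
    for (int k = 0; k < L; ++k)
      n += (axis == 0) ? mask(g, k) : mask(k, g);
    nc.nvalid(g) = n;
  }
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& hc = nc.xhat.slice(c);
    for (int g = 0; g < L; ++g) {
      uword n = nc.nvalid(g);
      if (n < 2) {
        if (axis == 0) hc.row(g) = xc.row(g);
        else hc.col(g) = xc.col(g);
        continue;
      }
      double mu = 0;
      for (int k = 0; k < L; ++k) {
        bool m = (axis == 0) ? mask(g, k) : mask(k, g);
        if (m) mu += (axis == 0) ? xc(g, k) : xc(k, g);
      }
      mu /= n;
      double var = 0;
      for (int k = 0; k < L; ++k) {
        bool m = (axis == 0) ? mask(g, k) : mask(k, g);
        if (m) {
          double v = ((axis == 0) ? xc(g, k) : xc(k, g)) - mu;
          var += v * v;
        }
      }
      var /= n;
      double sg = std::sqrt(var), s = sg + eps;
      nc.sigma(g, c) = sg;
      nc.s(g, c) = s;
      if (axis == 0) hc.row(g) = (xc.row(g) - mu) / s;
      else hc.col(g) = (xc.col(g) - mu) / s;
    }
  }
}

// dxhat -> dx. All entries of a group are standardized with the masked
// mean/std, so the mean/std gradient terms collect over the whole group
// but only flow back into masked entries.
void norm_backward(const cube& dxhat, const NormCache& nc, const umat& mask,
                   cube& dx_acc) {
  const int L = dxhat.n_rows, C = dxhat.n_slices;
  if (nc.axis == 2) {
    uword n = nc.nvalid(0);
    for (int c = 0; c < C; ++c) {
      const mat& dh = dxhat.slice(c);
      if (n < 2) { dx_acc.slice(c) += dh; continue; }
      const mat& hc = nc.xhat.slice(c);
      double s = nc.s(0, c), sg = nc.sigma(0, c);
      double S1 = accu(dh), S2 = accu(dh % hc);
      mat& out = dx_acc.slice(c);
      for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i) {
          double v = dh(i, j) / s;
          if (mask(i, j)) {
            v -= S1 / (double(n) * s);
            if (sg > 1e-12) v -= hc(i, j) * S2 / (double(n) * sg);
          }
          out(i, j) += v;
        }
    }
    return;
  }
  for (int c = 0; c < C; ++c) {
    const mat& dh = dxhat.slice(c);
    const mat& hc = nc.xhat.slice(c);
    mat& out = dx_acc.slice(c);
    for (int g = 0; g < L; ++g) {
      uword n = nc.nvalid(g);
      if (n < 2) {
        for (int k = 0; k < L; ++k) {
          if (nc.axis == 0) out(g, k) += dh(g, k);
          else out(k, g) += dh(k, g);
        }
        continue;
      }
      double s = nc.s(g, c), sg = nc.sigma(g, c);
      double S1 = 0, S2 = 0;
      for (int k = 0; k < L; ++k) {
        double d = (nc.axis == 0) ? dh(g, k) : dh(k, g);
        double h = (nc.axis == 0) ? hc(g, k) : hc(k, g);
        S1 += d;
        S2 += d * h;
      }
      for (int k = 0; k < L; ++k) {
        bool m = (nc.axis == 0) ? mask(g, k) : mask(k, g);
        double d = (nc.axis == 0) ? dh(g, k) : dh(k, g);
        double h = (nc.axis == 0) ? hc(g, k) : hc(k, g);
        double v = d / s;
        if (m) {
          v -= S1 / (double(n) * s);
          if (sg > 1e-12) v -= h * S2 / (double(n) * sg);
        }
        if (nc.axis == 0) out(g, k) += v;
        else out(k, g) += v;
      }
    }
  }
}

// ---------------------------------------------------------------------
// 3x3 convolution, zero padded, via im2col + GEMM

void im2col3(const cube& x, mat& cols) {
  const int L = x.n_rows, C = x.n_slices, N = L * L;
  cols.set_size(9 * C, N);
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int r = (di + 1) + 3 * (dj + 1) + 9 * c;
        for (int j = 0; j < L; ++j) {
          int js = j + dj;
          if (js < 0 || js >= L) continue;
          for (int i = 0; i < L; ++i) {
            int is = i + di;
            if (is < 0 || is >= L) continue;
            cols(r, i + L * j) = xc(is, js);
          }
        }
      }
  }
}

void col2im3(const mat& dcols, int L, int C, cube& dx) {
  dx.zeros(L, L, C);
  for (int c = 0; c < C; ++c) {
    mat& xc = dx.slice(c);
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int r = (di + 1) + 3 * (dj + 1) + 9 * c;
        for (int j = 0; j < L; ++j) {
          int js = j + dj;
          if (js < 0 || js >= L) continue;
          for (int i = 0; i < L; ++i) {
            int is = i + di;
            if (is < 0 || is >= L) continue;
            xc(is, js) += dcols(r, i + L * j);
          }
        }
      }
  }
}

// y(L,L,Cout) = conv3x3(x) with weight view W (9*Cin x Cout), bias b.
void conv3_forward(const cube& x, const mat& W, const vec& b, cube& y) {
  const int L = x.n_rows, N = L * L, Cout = W.n_cols;
  mat cols;
  im2col3(x, cols);
  y.set_size(L, L, Cout);
  mat yv(y.memptr(), N, Cout, false, true);
  yv = cols.t() * W;
  yv.each_row() += b.t();
}

void conv3_backward(const cube& x, const mat& W, const cube& dy,
                    mat& dW, vec& db, cube& dx) {
  const int L = x.n_rows, N = L * L, Cout = W.n_cols,
            Cin = x.n_slices;
  mat cols;
  im2col3(x, cols);
  const mat dyv(const_cast<double*>(dy.memptr()), N, Cout, false, true);
  dW = cols * dyv;
  db = sum(dyv, 0).t();
  mat dcols = W * dyv.t();
  col2im3(dcols, L, Cin, dx);
}

inline void lrelu_inplace(cube& x, double slope) {
  for (uword k = 0; k < x.n_elem; ++k)
    if (x(k) < 0) x(k) *= slope;
}

// gradient through LReLU given its *output* a (slope > 0 so sign(a) ==
// sign of the pre-activation)
inline void lrelu_backward(const cube& a, cube& da, double slope) {
  for (uword k = 0; k < a.n_elem; ++k)
    if (a(k) < 0) da(k) *= slope;
}

// ---------------------------------------------------------------------
// block forward / backward

struct BlockCache {
  NormCache n1r, n1c, n1i, n2;
  cube xhat1;  // combined standardized input of repeat 1 (pre-affine)
  cube a1, a2; // post-LReLU activations (conv inputs)
};

void affine_apply(const cube& xhat, const double* g, const double* be,
                  cube& y) {
  const int C = xhat.n_slices;
  y.set_size(xhat.n_rows, xhat.n_cols, C);
  for (int c = 0; c < C; ++c)
    y.slice(c) = g[c] * xhat.slice(c) + be[c];
}

void block_forward(const cube& x, const double* p, const ParamView& pv,
                   int b, const Cfg& cfg, const umat& mask, cube& out,
                   BlockCache* bc) {
  const int C = cfg.C;
  BlockCache local;
  BlockCache& cache = bc ? *bc : local;
  // repeat 1 normalization: (RN + CN)/2 or IN
  if (cfg.use_rncn) {
    norm_forward(x, mask, cfg.eps, 0, cache.n1r);
    norm_forward(x, mask, cfg.eps, 1, cache.n1c);
    cache.xhat1 = 0.5 * (cache.n1r.xhat + cache.n1c.xhat);
  } else {
    norm_forward(x, mask, cfg.eps, 2, cache.n1i);
    cache.xhat1 = cache.n1i.xhat;
  }
  cube y1;
  affine_apply(cache.xhat1, p + pv.g1(b), p + pv.be1(b), y1);
  lrelu_inplace(y1, cfg.slope);
  cache.a1 = y1;
  const mat W1(const_cast<double*>(p + pv.W1(b)), 9 * C, C, false, true);
  const vec b1(const_cast<double*>(p + pv.b1(b)), C, false, true);
  cube c1;
  conv3_forward(cache.a1, W1, b1, c1);
  // repeat 2 normalization: IN
  norm_forward(c1, mask, cfg.eps, 2, cache.n2);
  cube y2;
  affine_apply(cache.n2.xhat, p + pv.g2(b), p + pv.be2(b), y2);
  lrelu_inplace(y2, cfg.slope);
  cache.a2 = y2;
  const mat W2(const_cast<double*>(p + pv.W2(b)), 9 * C, C, false, true);
  const vec b2(const_cast<double*>(p + pv.b2(b)), C, false, true);
  cube c2;
  conv3_forward(cache.a2, W2, b2, c2);
  out = x + c2;  // shortcut connection
}

// dY: gradient w.r.t. block output; dX: gradient w.r.t. block input
// (overwritten); grads written into gr at the block's offsets.
void block_backward(const cube& dY, const BlockCache& cache,
                    const double* p, double* gr, const ParamView& pv,
                    int b, const Cfg& cfg, const umat& mask, cube& dX) {
  const int C = cfg.C, L = dY.n_rows;
  // conv2
  const mat W2(const_cast<double*>(p + pv.W2(b)), 9 * C, C, false, true);
  mat dW2;
  vec db2;
  cube da2;
  conv3_backward(cache.a2, W2, dY, dW2, db2, da2);
  std::copy(dW2.memptr(), dW2.memptr() + dW2.n_elem, gr + pv.W2(b));
  std::copy(db2.memptr(), db2.memptr() + C, gr + pv.b2(b));
  // LReLU 2
  lrelu_backward(cache.a2, da2, cfg.slope);
  // affine 2 (gain/bias of IN)
  cube dxhat2(L, L, C);
  for (int c = 0; c < C; ++c) {
    gr[pv.g2(b) + c] = accu(da2.slice(c) % cache.n2.xhat.slice(c));
    gr[pv.be2(b) + c] = accu(da2.slice(c));
    dxhat2.slice(c) = p[pv.g2(b) + c] * da2.slice(c);
  }
  cube dc1(L, L, C, fill::zeros);
  norm_backward(dxhat2, cache.n2, mask, dc1);
  // conv1
  const mat W1(const_cast<double*>(p + pv.W1(b)), 9 * C, C, false, true);
  mat dW1;
  vec db1;
  cube da1;
  conv3_backward(cache.a1, W1, dc1, dW1, db1, da1);
  std::copy(dW1.memptr(), dW1.memptr() + dW1.n_elem, gr + pv.W1(b));
  std::copy(db1.memptr(), db1.memptr() + C, gr + pv.b1(b));
  // LReLU 1
  lrelu_backward(cache.a1, da1, cfg.slope);
  // affine 1
  cube dxhat1(L, L, C);
  for (int c = 0; c < C; ++c) {
    gr[pv.g1(b) + c] = accu(da1.slice(c) % cache.xhat1.slice(c));
    gr[pv.be1(b) + c] = accu(da1.slice(c));
    dxhat1.slice(c) = p[pv.g1(b) + c] * da1.slice(c);
  }
  dX = dY;  // shortcut
  if (cfg.use_rncn) {
    cube half = 0.5 * dxhat1;
    norm_backward(half, cache.n1r, mask, dX);
    norm_backward(half, cache.n1c, mask, dX);
  } else {
    norm_backward(dxhat1, cache.n1i, mask, dX);
  }
}

// ---------------------------------------------------------------------

cube as_cube(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected an L x L x C array");
  return cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

umat as_umat(const Rcpp::LogicalMatrix& m) {
  umat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = m(i, j) ? 1 : 0;
  return out;
}

inline double sigmoid(double z) {
  return z >= 0 ? 1.0 / (1.0 + std::exp(-z)) : std::exp(z) / (1.0 + std::exp(z));
}

// trunk forward shared by prediction and training: embed + blocks.
// Returns final hidden state y and the head logits z.
void trunk_forward(const double* p, const ParamView& pv, const cube& x,
                   const umat& mask, const Cfg& cfg, cube& y, mat& z,
                   std::vector<BlockCache>* caches) {
  const int L = x.n_rows, N = L * L;
  const mat Win(const_cast<double*>(p + pv.win()), cfg.Cin, cfg.C, false,
                true);
  const vec bin(const_cast<double*>(p + pv.bin()), cfg.C, false, true);
  const mat xv(const_cast<double*>(x.memptr()), N, cfg.Cin, false, true);
  y.set_size(L, L, cfg.C);
  {
    mat yv(y.memptr(), N, cfg.C, false, true);
    yv = xv * Win;
    yv.each_row() += bin.t();
  }
  for (int b = 0; b < cfg.B; ++b) {
    cube out;
    block_forward(y, p, pv, b, cfg, mask,
                  out, caches ? &(*caches)[b] : nullptr);
    y = out;
  }
  const vec wout(const_cast<double*>(p + pv.wout()), cfg.C, false, true);
  double bout = p[pv.bout()];
  const mat yv(const_cast<double*>(y.memptr()), N, cfg.C, false, true);
  vec zv = yv * wout + bout;
  z = mat(zv.memptr(), L, L);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector norm_forward_cpp(Rcpp::NumericVector x,
                                     Rcpp::LogicalMatrix mask, double eps,
                                     int axis, Rcpp::NumericVector gain,
                                     Rcpp::NumericVector bias) {
  cube xc = as_cube(x);
  umat m = as_umat(mask);
  NormCache nc;
  norm_forward(xc, m, eps, axis, nc);
  cube out;
  affine_apply(nc.xhat, gain.begin(), bias.begin(), out);
  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = x.attr("dim");
  return res;
}

// [[Rcpp::export]]
Rcpp::NumericVector resnet_block_cpp(Rcpp::NumericVector x,
                                     Rcpp::NumericVector block_params,
                                     Rcpp::LogicalMatrix mask,
                                     Rcpp::List cfg_list) {
  Cfg cfg = parse_cfg(cfg_list);
  cube xc = as_cube(x);
  if ((int)xc.n_slices != cfg.C) Rcpp::stop("channel mismatch");
  // block_params holds one block's weights in the standard layout
  ParamView pv(cfg.Cin, cfg.C, 1);
  if ((size_t)block_params.size() != pv.block_sz)
    Rcpp::stop("block parameter vector has wrong length");
  std::vector<double> full(pv.total, 0.0);
  std::copy(block_params.begin(), block_params.end(),
            full.begin() + pv.block(0));
  umat m = as_umat(mask);
  cube out;
  block_forward(xc, full.data(), pv, 0, cfg, m, out, nullptr);
  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = x.attr("dim");
  return res;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix pairnet_forward_cpp(Rcpp::NumericVector params,
                                        Rcpp::NumericVector x,
                                        Rcpp::LogicalMatrix mask,
                                        Rcpp::List cfg_list) {
  Cfg cfg = parse_cfg(cfg_list);
  cube xc = as_cube(x);
  if ((int)xc.n_slices != cfg.Cin)
    Rcpp::stop("feature tensor has %d channels, model expects %d",
               (int)xc.n_slices, cfg.Cin);
  ParamView pv(cfg.Cin, cfg.C, cfg.B);
  if ((size_t)params.size() != pv.total)
    Rcpp::stop("parameter vector has wrong length");
  umat m = as_umat(mask);
  const int L = xc.n_rows;
  cube y;
  mat z;
  trunk_forward(params.begin(), pv, xc, m, cfg, y, z, nullptr);
  Rcpp::NumericMatrix out(L, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      if (!m(i, j)) { out(i, j) = 0; continue; }
      out(i, j) = 0.5 * (sigmoid(z(i, j)) + sigmoid(z(j, i)));
    }
  return out;
}

// [[Rcpp::export]]
Rcpp::List pairnet_loss_grad_cpp(Rcpp::NumericVector params,
                                 Rcpp::NumericVector x,
                                 Rcpp::LogicalMatrix mask,
                                 Rcpp::NumericMatrix labels,
                                 Rcpp::List cfg_list, double pos_weight) {
  Cfg cfg = parse_cfg(cfg_list);
  cube xc = as_cube(x);
  if ((int)xc.n_slices != cfg.Cin) Rcpp::stop("channel mismatch");
  ParamView pv(cfg.Cin, cfg.C, cfg.B);
  if ((size_t)params.size() != pv.total)
    Rcpp::stop("parameter vector has wrong length");
  umat m = as_umat(mask);
  const int L = xc.n_rows, N = L * L;
  const double* p = params.begin();

  std::vector<BlockCache> caches(cfg.B);
  cube y;
  mat z;
  trunk_forward(p, pv, xc, m, cfg, y, z, &caches);

  // masked, weighted binary cross-entropy on the symmetrized probability
  mat sig(L, L), P(L, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i)
      sig(i, j) = sigmoid(z(i, j));
  P = 0.5 * (sig + sig.t());
  const double pc = 1e-12;
  double loss = 0, wsum = 0;
  mat dP(L, L, fill::zeros);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      if (!m(i, j)) continue;
      double yl = labels(i, j);
      double w = yl > 0.5 ? pos_weight : 1.0;
      double pij = std::min(std::max(P(i, j), pc), 1.0 - pc);
      loss += w * (-(yl * std::log(pij) + (1 - yl) * std::log(1 - pij)));
      dP(i, j) = w * (pij - yl) / (pij * (1 - pij));
      wsum += w;
    }
  if (wsum > 0) {
    loss /= wsum;
    dP /= wsum;
  }
  // back through symmetrization and the logistic
  mat dz(L, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i)
      dz(i, j) = 0.5 * (dP(i, j) + dP(j, i)) * sig(i, j) * (1 - sig(i, j));

  Rcpp::NumericVector grad(params.size());
  double* gr = grad.begin();

  // head
  const mat yv(const_cast<double*>(y.memptr()), N, cfg.C, false, true);
  const vec dzv(dz.memptr(), N, false, true);
  vec dwout = yv.t() * dzv;
  std::copy(dwout.memptr(), dwout.memptr() + cfg.C, gr + pv.wout());
  gr[pv.bout()] = accu(dz);
  const vec wout(const_cast<double*>(p + pv.wout()), cfg.C, false, true);
  cube dY(L, L, cfg.C);
  {
    mat dYv(dY.memptr(), N, cfg.C, false, true);
    dYv = dzv * wout.t();
  }
  // blocks in reverse
  for (int b = cfg.B - 1; b >= 0; --b) {
    cube dX;
    block_backward(dY, caches[b], p, gr, pv, b, cfg, m, dX);
    dY = dX;
  }
  // embed
  const mat xv(const_cast<double*>(xc.memptr()), N, cfg.Cin, false, true);
  const mat dEv(const_cast<double*>(dY.memptr()), N, cfg.C, false, true);
  mat dWin = xv.t() * dEv;
  std::copy(dWin.memptr(), dWin.memptr() + dWin.n_elem, gr + pv.win());
  vec dbin = sum(dEv, 0).t();
  std::copy(dbin.memptr(), dbin.memptr() + cfg.C, gr + pv.bin());

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}
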