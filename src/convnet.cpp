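// Convolutional primitives for the multi-task CNN.
//
// Layout convention shared with the R side: a batch of m images with C
// channels of size H x W is an arma::cube with n_slices = m * C and slice
// index s = i * C + c (channel fastest). Kernels are stored im2col-style as
// a (9 * C_in) x C_out matrix whose rows are ordered channel-major, with
// the 3x3 window flattened column-major within each channel block.
//
// The five-stage backbone (conv3x3 + ReLU, max-pool after the first four
// stages) is fused into a single forward / backward pair that keeps its
// layer caches in C++ between the two calls, avoiding per-layer array
// copies across the R boundary. The single-layer primitives are exported
// as well for oracle tests.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::_;

// im2col for one sample (3x3 window, zero padding 1, stride 1)
static void im2col3(const cube& X, uword base, uword Cin, mat& P) {
  const uword H = X.n_rows, W = X.n_cols;
  for (uword c = 0; c < Cin; ++c) {
    mat pad(H + 2, W + 2, fill::zeros);
    pad.submat(1, 1, H, W) = X.slice(base + c);
    const uword col0 = c * 9;
    for (uword dj = 0; dj < 3; ++dj)
      for (uword di = 0; di < 3; ++di)
        P.col(col0 + dj * 3 + di) =
            vectorise(pad.submat(di, dj, di + H - 1, dj + W - 1));
  }
}

static cube conv3_fwd(const cube& X, const mat& K, const vec& b, int m) {
  const uword H = X.n_rows, W = X.n_cols;
  const uword Cin = X.n_slices / m, Cout = K.n_cols;
  cube Y(H, W, (uword)m * Cout);
  mat P(H * W, 9 * Cin);
  for (uword i = 0; i < (uword)m; ++i) {
    im2col3(X, i * Cin, Cin, P);
    mat O = P * K;
    O.each_row() += b.t();
    for (uword c = 0; c < Cout; ++c)
      Y.slice(i * Cout + c) = reshape(O.col(c), H, W);
  }
  return Y;
}

static void conv3_bwd(const cube& X, const mat& K, const cube& dY, int m,
                      cube& dX, mat& dK, vec& db) {
  const uword H = X.n_rows, W = X.n_cols;
  const uword Cin = X.n_slices / m, Cout = K.n_cols;
  dK.zeros(9 * Cin, Cout);
  db.zeros(Cout);
  dX.set_size(H, W, X.n_slices);
  mat P(H * W, 9 * Cin);
  mat G(H * W, Cout);
  for (uword i = 0; i < (uword)m; ++i) {
    im2col3(X, i * Cin, Cin, P);
    for (uword c = 0; c < Cout; ++c)
      G.col(c) = vectorise(dY.slice(i * Cout + c));
    dK += P.t() * G;
    db += sum(G, 0).t();
    mat dP = G * K.t();  // (H*W) x (9*Cin), scatter back (col2im)
    for (uword c = 0; c < Cin; ++c) {
      mat pad(H + 2, W + 2, fill::zeros);
      const uword col0 = c * 9;
      for (uword dj = 0; dj < 3; ++dj)
        for (uword di = 0; di < 3; ++di)
          pad.submat(di, dj, di + H - 1, dj + W - 1) +=
              reshape(dP.col(col0 + dj * 3 + di), H, W);
      dX.slice(i * Cin + c) = pad.submat(1, 1, H, W);
    }
  }
}

// 2x2 max pooling, stride 2, floor division (odd trailing row/col dropped).
// Ties resolved to the first element in column-major window order. idx
// stores the 0-based within-slice linear index of each selected element.
static void maxpool2_fwd(const cube& X, cube& Y, ucube& idx) {
  const uword H = X.n_rows, S = X.n_slices;
  const uword Ho = X.n_rows / 2, Wo = X.n_cols / 2;
  Y.set_size(Ho, Wo, S);
  idx.set_size(Ho, Wo, S);
  for (uword s = 0; s < S; ++s) {
    const mat& A = X.slice(s);
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        const uword bi = 2 * i, bj = 2 * j;
        double best = A(bi, bj);
        uword ii = bi, jj = bj;
        if (A(bi + 1, bj) > best) { best = A(bi + 1, bj); ii = bi + 1; jj = bj; }
        if (A(bi, bj + 1) > best) { best = A(bi, bj + 1); ii = bi; jj = bj + 1; }
        if (A(bi + 1, bj + 1) > best) { best = A(bi + 1, bj + 1); ii = bi + 1; jj = bj + 1; }
        Y(i, j, s) = best;
        idx(i, j, s) = jj * H + ii;
      }
    }
  }
}

static void maxpool2_bwd(const cube& dY, const ucube& idx, uword H, uword W,
                         cube& dX) {
  dX.zeros(H, W, dY.n_slices);
  for (uword s = 0; s < dY.n_slices; ++s) {
    double* slab = dX.slice_memptr(s);
    const mat& G = dY.slice(s);
    const umat& I = idx.slice(s);
    for (uword j = 0; j < dY.n_cols; ++j)
      for (uword i = 0; i < dY.n_rows; ++i)
        slab[I(i, j)] += G(i, j);
  }
}

// ---- exported single-layer primitives (oracle tests) ----

// [[Rcpp::export]]
arma::cube conv3_forward(const arma::cube& X, const arma::mat& K,
                         const arma::vec& b, int m) {
  return conv3_fwd(X, K, b, m);
}

// [[Rcpp::export]]
List conv3_backward(const arma::cube& X, const arma::mat& K,
                    const arma::cube& dY, int m) {
  cube dX; mat dK; vec db;
  conv3_bwd(X, K, dY, m, dX, dK, db);
  return List::create(_["dx"] = dX, _["dk"] = dK, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_forward(const arma::cube& X) {
  cube Y; ucube idx;
  maxpool2_fwd(X, Y, idx);
  return List::create(_["out"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::cube& dY, const arma::ucube& idx,
                             int H, int W) {
  cube dX;
  maxpool2_bwd(dY, idx, (uword)H, (uword)W, dX);
  return dX;
}

// ---- fused backbone with in-C++ caches ----

namespace {
struct StackCache {
  int m = 0;
  int n_layers = 0;
  std::vector<cube> in;     // input of each conv layer (post previous pool)
  std::vector<cube> relu;   // post-ReLU conv output of each layer
  std::vector<ucube> pidx;  // pooling argmax of the pooled layers
};
StackCache g_cache;
}  // namespace

// Forward through the conv backbone; returns the flattened features as an
// m x (ch * side^2) matrix (row = sample, features channel-major). With
// keep_cache the per-layer inputs, ReLU outputs and pooling indices are
// retained in C++ for the next cnn_backward_stack call.
// [[Rcpp::export]]
arma::mat cnn_forward_stack(const arma::cube& X, const Rcpp::List& Ks,
                            const Rcpp::List& bs, int m, bool keep_cache) {
  const int L = Ks.size();
  cube cur = X;
  if (keep_cache) {
    g_cache.m = m;
    g_cache.n_layers = L;
    g_cache.in.assign(L, cube());
    g_cache.relu.assign(L, cube());
    g_cache.pidx.assign(L - 1, ucube());
  }
  for (int k = 0; k < L; ++k) {
    const mat K = Rcpp::as<mat>(Ks[k]);
    const vec b = Rcpp::as<vec>(bs[k]);
    if (keep_cache) g_cache.in[k] = cur;
    cube Y = conv3_fwd(cur, K, b, m);
    Y.transform([](double v) { return v > 0 ? v : 0.0; });
    if (keep_cache) g_cache.relu[k] = Y;
    if (k < L - 1) {
      cube P; ucube idx;
      maxpool2_fwd(Y, P, idx);
      if (keep_cache) g_cache.pidx[k] = idx;
      cur = P;
    } else {
      cur = Y;
    }
  }
  const uword ch = cur.n_slices / m;
  const uword px = cur.n_rows * cur.n_cols;
  mat F((uword)m, ch * px);
  for (uword i = 0; i < (uword)m; ++i)
    for (uword c = 0; c < ch; ++c)
      F(span(i, i), span(c * px, (c + 1) * px - 1)) =
          reshape(cur.slice(i * ch + c), 1, px);
  return F;
}

// Backward through the cached backbone. dF is the gradient at the
// flattened features; returns per-layer kernel and bias gradients.
// [[Rcpp::export]]
List cnn_backward_stack(const arma::mat& dF, const Rcpp::List& Ks) {
  const int L = Ks.size();
  const int m = g_cache.m;
  if (m == 0 || g_cache.n_layers != L)
    Rcpp::stop("no cached forward pass for this backbone");
  const cube& last = g_cache.relu[L - 1];
  const uword ch = last.n_slices / m;
  const uword px = last.n_rows * last.n_cols;
  cube dcur(last.n_rows, last.n_cols, last.n_slices);
  for (uword i = 0; i < (uword)m; ++i)
    for (uword c = 0; c < ch; ++c)
      dcur.slice(i * ch + c) = reshape(
          dF(span(i, i), span(c * px, (c + 1) * px - 1)),
          last.n_rows, last.n_cols);
  Rcpp::List dKs(L), dbs(L);
  for (int k = L - 1; k >= 0; --k) {
    if (k < L - 1) {
      const cube& rl = g_cache.relu[k];
      cube up;
      maxpool2_bwd(dcur, g_cache.pidx[k], rl.n_rows, rl.n_cols, up);
      dcur = up;
    }
    const cube& rl = g_cache.relu[k];
    for (uword s = 0; s < dcur.n_slices; ++s)
      dcur.slice(s) %= conv_to<mat>::from(rl.slice(s) > 0);
    const mat K = Rcpp::as<mat>(Ks[k]);
    cube dX; mat dK; vec db;
    conv3_bwd(g_cache.in[k], K, dcur, m, dX, dK, db);
    dKs[k] = dK;
    dbs[k] = db;
    dcur = dX;
  }
  g_cache.m = 0;  // caches consumed
  g_cache.in.clear(); g_cache.relu.clear(); g_cache.pidx.clear();
  return List::create(_["dk"] = dKs, _["db"] = dbs);
}

// Separable binomial (approximately Gaussian) smoothing with [1,2,1]/4 in
// each direction, applied `passes` times with edge replication. Used by the
// synthetic nodule generator for texture fields.
// [[Rcpp::export]]
arma::mat smooth121(const arma::mat& A, int passes) {
  mat cur = A;
  const uword H = A.n_rows, W = A.n_cols;
  for (int p = 0; p < passes; ++p) {
    mat tmp(H, W);
    for (uword j = 0; j < W; ++j) {
      for (uword i = 0; i < H; ++i) {
        const uword im = i == 0 ? 0 : i - 1, ip = i == H - 1 ? H - 1 : i + 1;
        tmp(i, j) = 0.25 * (cur(im, j) + 2.0 * cur(i, j) + cur(ip, j));
      }
    }
    for (uword i = 0; i < H; ++i) {
      for (uword j = 0; j < W; ++j) {
        const uword jm = j == 0 ? 0 : j - 1, jp = j == W - 1 ? W - 1 : j + 1;
        cur(i, j) = 0.25 * (tmp(i, jm) + 2.0 * tmp(i, j) + tmp(i, jp));
      }
    }
  }
  return cur;
}
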