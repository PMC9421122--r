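// Fixed small CNN for binary spectrogram-image classification:
// conv(32, 3x3, stride 1, valid, ReLU) -> maxpool(2x2, stride 2) ->
// conv(64, 3x3, stride 1, valid, ReLU) -> maxpool(2x2, stride 2) ->
// flatten -> dense(64, ReLU) -> dense(1, sigmoid).
// Trained with Adam on binary cross-entropy. Whole minibatches are laid
// out as concatenated im2col blocks so every layer runs as one large
// sgemm. Single-threaded, float32, bit-deterministic for fixed weights
// and example order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Dims {
  int H, W, C;
  int H1, W1, Hp1, Wp1, H2, W2, Hp2, Wp2;
  int L1, Lp1, L2, Lp2, D;
};

Dims make_dims(int H, int W, int C) {
  Dims d;
  d.H = H; d.W = W; d.C = C;
  d.H1 = H - 2; d.W1 = W - 2;
  d.Hp1 = d.H1 / 2; d.Wp1 = d.W1 / 2;
  d.H2 = d.Hp1 - 2; d.W2 = d.Wp1 - 2;
  d.Hp2 = d.H2 / 2; d.Wp2 = d.W2 / 2;
  if (d.H1 < 1 || d.W1 < 1 || d.H2 < 1 || d.W2 < 1 || d.Hp2 < 1 || d.Wp2 < 1)
    Rcpp::stop("input image too small for the fixed architecture");
  d.L1 = d.H1 * d.W1; d.Lp1 = d.Hp1 * d.Wp1;
  d.L2 = d.H2 * d.W2; d.Lp2 = d.Hp2 * d.Wp2;
  d.D = 64 * d.Lp2;
  return d;
}

// Feature maps: K x (h*w) blocks, spatial index idx = x*h + y, one block
// per batch image, concatenated along columns.

void im2col3(const fmat& in, int in0, int h, int w, fmat& out, int out0) {
  const int ho = h - 2, wo = w - 2;
  const int K = in.n_rows;
  for (int x = 0; x < wo; ++x)
    for (int y = 0; y < ho; ++y) {
      float* dst = out.colptr(out0 + x * ho + y);
      for (int dx = 0; dx < 3; ++dx)
        for (int dy = 0; dy < 3; ++dy)
          std::memcpy(dst + (dx * 3 + dy) * K,
                      in.colptr(in0 + (x + dx) * h + (y + dy)),
                      K * sizeof(float));
    }
}

void col2im3(const fmat& dcol, int col0, int h, int w, fmat& din, int in0) {
  const int ho = h - 2, wo = w - 2;
  const int K = din.n_rows;
  for (int x = 0; x < wo; ++x)
    for (int y = 0; y < ho; ++y) {
      const float* src = dcol.colptr(col0 + x * ho + y);
      for (int dx = 0; dx < 3; ++dx)
        for (int dy = 0; dy < 3; ++dy) {
          float* dst = din.colptr(in0 + (x + dx) * h + (y + dy));
          const float* s = src + (dx * 3 + dy) * K;
          for (int k = 0; k < K; ++k) dst[k] += s[k];
        }
    }
}

// 2x2 stride-2 max pool (floor semantics) with argmax bookkeeping.
void maxpool(const fmat& in, int in0, int h, int w,
             fmat& out, umat& argmax, int out0) {
  const int hp = h / 2, wp = w / 2;
  const int K = in.n_rows;
  for (int x = 0; x < wp; ++x)
    for (int y = 0; y < hp; ++y) {
      const int oc = out0 + x * hp + y;
      const int c00 = in0 + (2 * x) * h + 2 * y;
      const int cands[4] = {c00, c00 + 1, c00 + h, c00 + h + 1};
      float* op = out.colptr(oc);
      uword* ap = argmax.colptr(oc);
      const float* p0 = in.colptr(cands[0]);
      const float* p1 = in.colptr(cands[1]);
      const float* p2 = in.colptr(cands[2]);
      const float* p3 = in.colptr(cands[3]);
      for (int k = 0; k < K; ++k) {
        float best = p0[k]; uword bi = cands[0];
        if (p1[k] > best) { best = p1[k]; bi = cands[1]; }
        if (p2[k] > best) { best = p2[k]; bi = cands[2]; }
        if (p3[k] > best) { best = p3[k]; bi = cands[3]; }
        op[k] = best; ap[k] = bi;
      }
    }
}

inline void relu_cols(fmat& z, size_t ncols) {
  float* p = z.memptr();
  const size_t n = z.n_rows * ncols;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// Zero gradient entries where the forward post-ReLU activation is zero
// (equivalently pre-activation <= 0, since ReLU output is stored).
inline void relu_mask_cols(fmat& g, const fmat& z, size_t ncols) {
  float* p = g.memptr();
  const float* q = z.memptr();
  const size_t n = g.n_rows * ncols;
  for (size_t i = 0; i < n; ++i) if (q[i] <= 0.0f) p[i] = 0.0f;
}

struct Weights {
  fmat W1, W2, W3, W4;
  fvec b1, b2, b3, b4;
  void zeros_like(const Weights& o) {
    W1 = zeros<fmat>(size(o.W1)); W2 = zeros<fmat>(size(o.W2));
    W3 = zeros<fmat>(size(o.W3)); W4 = zeros<fmat>(size(o.W4));
    b1 = zeros<fvec>(size(o.b1)); b2 = zeros<fvec>(size(o.b2));
    b3 = zeros<fvec>(size(o.b3)); b4 = zeros<fvec>(size(o.b4));
  }
};

Weights weights_from_list(const Rcpp::List& w) {
  Weights wt;
  wt.W1 = conv_to<fmat>::from(Rcpp::as<mat>(w["W1"]));
  wt.W2 = conv_to<fmat>::from(Rcpp::as<mat>(w["W2"]));
  wt.W3 = conv_to<fmat>::from(Rcpp::as<mat>(w["W3"]));
  wt.W4 = conv_to<fmat>::from(Rcpp::as<mat>(w["W4"]));
  wt.b1 = conv_to<fvec>::from(Rcpp::as<vec>(w["b1"]));
  wt.b2 = conv_to<fvec>::from(Rcpp::as<vec>(w["b2"]));
  wt.b3 = conv_to<fvec>::from(Rcpp::as<vec>(w["b3"]));
  wt.b4 = conv_to<fvec>::from(Rcpp::as<vec>(w["b4"]));
  return wt;
}

Rcpp::List weights_to_list(const Weights& wt) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = conv_to<mat>::from(wt.W1),
    Rcpp::Named("b1") = conv_to<vec>::from(wt.b1),
    Rcpp::Named("W2") = conv_to<mat>::from(wt.W2),
    Rcpp::Named("b2") = conv_to<vec>::from(wt.b2),
    Rcpp::Named("W3") = conv_to<mat>::from(wt.W3),
    Rcpp::Named("b3") = conv_to<vec>::from(wt.b3),
    Rcpp::Named("W4") = conv_to<mat>::from(wt.W4),
    Rcpp::Named("b4") = conv_to<vec>::from(wt.b4));
}

struct Workspace {
  fmat in, A1, Z1, P1, A2, Z2, P2, F, Z3, Hh;
  umat arg1, arg2;
  fmat dZ1, dZ2, dA2, dP1, dP2, dH, dF;
  frowvec z4, o;
  Workspace(const Dims& d, int cap) {
    in.set_size(d.C, (size_t)d.H * d.W * cap);
    A1.set_size(9 * d.C, (size_t)d.L1 * cap);
    Z1.set_size(32, (size_t)d.L1 * cap);
    P1.set_size(32, (size_t)d.Lp1 * cap);
    arg1.set_size(32, (size_t)d.Lp1 * cap);
    A2.set_size(288, (size_t)d.L2 * cap);
    Z2.set_size(64, (size_t)d.L2 * cap);
    P2.set_size(64, (size_t)d.Lp2 * cap);
    arg2.set_size(64, (size_t)d.Lp2 * cap);
    dZ1.set_size(32, (size_t)d.L1 * cap);
    dZ2.set_size(64, (size_t)d.L2 * cap);
    dA2.set_size(288, (size_t)d.L2 * cap);
    dP1.set_size(32, (size_t)d.Lp1 * cap);
  }
};

void load_image(const double* x, const Dims& d, int n, fmat& in, int b) {
  const long long plane = (long long)d.H * d.W;
  const long long off = (long long)n * plane * d.C;
  const long long base = (long long)b * plane;
  for (int c = 0; c < d.C; ++c) {
    const double* src = x + off + c * plane;
    for (long long i = 0; i < plane; ++i) in(c, base + i) = (float)src[i];
  }
}

void forward(const Weights& wt, const Dims& d, Workspace& ws, int bn) {
  const size_t l1 = (size_t)d.L1 * bn, l2 = (size_t)d.L2 * bn;
  for (int b = 0; b < bn; ++b)
    im2col3(ws.in, b * d.H * d.W, d.H, d.W, ws.A1, b * d.L1);
  ws.Z1.head_cols(l1) = wt.W1 * ws.A1.head_cols(l1);
  ws.Z1.head_cols(l1).each_col() += wt.b1;
  relu_cols(ws.Z1, l1);
  for (int b = 0; b < bn; ++b)
    maxpool(ws.Z1, b * d.L1, d.H1, d.W1, ws.P1, ws.arg1, b * d.Lp1);
  for (int b = 0; b < bn; ++b)
    im2col3(ws.P1, b * d.Lp1, d.Hp1, d.Wp1, ws.A2, b * d.L2);
  ws.Z2.head_cols(l2) = wt.W2 * ws.A2.head_cols(l2);
  ws.Z2.head_cols(l2).each_col() += wt.b2;
  relu_cols(ws.Z2, l2);
  for (int b = 0; b < bn; ++b)
    maxpool(ws.Z2, b * d.L2, d.H2, d.W2, ws.P2, ws.arg2, b * d.Lp2);
  // flatten: block b of P2 (64 x Lp2, column-major) is column b of F
  ws.F = fmat(ws.P2.memptr(), d.D, bn);
  ws.Z3 = wt.W3 * ws.F;
  ws.Z3.each_col() += wt.b3;
  ws.Hh = ws.Z3;
  relu_cols(ws.Hh, bn);
  ws.z4 = wt.W4 * ws.Hh;
  ws.z4 += wt.b4(0);
  ws.o = 1.0f / (1.0f + exp(-ws.z4));
}

void backward(const Weights& wt, const Dims& d, Workspace& ws, int bn,
              const frowvec& dz4, Weights& g) {
  const size_t l1 = (size_t)d.L1 * bn, l2 = (size_t)d.L2 * bn;
  g.W4 += dz4 * ws.Hh.t();
  g.b4(0) += accu(dz4);
  ws.dH = wt.W4.t() * dz4;
  relu_mask_cols(ws.dH, ws.Hh, bn);
  g.W3 += ws.dH * ws.F.t();
  g.b3 += sum(ws.dH, 1);
  ws.dF = wt.W3.t() * ws.dH;  // D x bn; reinterpret as 64 x (Lp2*bn)
  const fmat dP2(ws.dF.memptr(), 64, (size_t)d.Lp2 * bn);
  ws.dZ2.head_cols(l2).zeros();
  for (uword c = 0; c < dP2.n_cols; ++c) {
    const float* s = dP2.colptr(c);
    const uword* a = ws.arg2.colptr(c);
    for (uword k = 0; k < 64; ++k) ws.dZ2(k, a[k]) += s[k];
  }
  relu_mask_cols(ws.dZ2, ws.Z2, l2);
  g.W2 += ws.dZ2.head_cols(l2) * ws.A2.head_cols(l2).t();
  g.b2 += sum(ws.dZ2.head_cols(l2), 1);
  ws.dA2.head_cols(l2) = wt.W2.t() * ws.dZ2.head_cols(l2);
  ws.dP1.head_cols((size_t)d.Lp1 * bn).zeros();
  for (int b = 0; b < bn; ++b)
    col2im3(ws.dA2, b * d.L2, d.Hp1, d.Wp1, ws.dP1, b * d.Lp1);
  ws.dZ1.head_cols(l1).zeros();
  for (uword c = 0; c < (size_t)d.Lp1 * bn; ++c) {
    const float* s = ws.dP1.colptr(c);
    const uword* a = ws.arg1.colptr(c);
    for (uword k = 0; k < 32; ++k) ws.dZ1(k, a[k]) += s[k];
  }
  relu_mask_cols(ws.dZ1, ws.Z1, l1);
  g.W1 += ws.dZ1.head_cols(l1) * ws.A1.head_cols(l1).t();
  g.b1 += sum(ws.dZ1.head_cols(l1), 1);
}

struct Adam {
  Weights m, v;
  double t = 0;
  Adam(const Weights& wt) { m.zeros_like(wt); v.zeros_like(wt); }
  template <typename T>
  void step_one(T& w, const T& g, T& mm, T& vv,
                float lr, float b1, float b2, float eps, float bc1, float bc2) {
    mm = b1 * mm + (1.0f - b1) * g;
    vv = b2 * vv + (1.0f - b2) * (g % g);
    w -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
  }
  void step(Weights& wt, const Weights& g,
            float lr, float b1, float b2, float eps) {
    t += 1;
    const float bc1 = 1.0f - std::pow(b1, (float)t);
    const float bc2 = 1.0f - std::pow(b2, (float)t);
    step_one(wt.W1, g.W1, m.W1, v.W1, lr, b1, b2, eps, bc1, bc2);
    step_one(wt.b1, g.b1, m.b1, v.b1, lr, b1, b2, eps, bc1, bc2);
    step_one(wt.W2, g.W2, m.W2, v.W2, lr, b1, b2, eps, bc1, bc2);
    step_one(wt.b2, g.b2, m.b2, v.b2, lr, b1, b2, eps, bc1, bc2);
    step_one(wt.W3, g.W3, m.W3, v.W3, lr, b1, b2, eps, bc1, bc2);
    step_one(wt.b3, g.b3, m.b3, v.b3, lr, b1, b2, eps, bc1, bc2);
    step_one(wt.W4, g.W4, m.W4, v.W4, lr, b1, b2, eps, bc1, bc2);
    step_one(wt.b4, g.b4, m.b4, v.b4, lr, b1, b2, eps, bc1, bc2);
  }
};

Dims dims_from_array(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 4 || dim[2] != 3)
    Rcpp::stop("images must be an H x W x 3 x N array");
  return make_dims(dim[0], dim[1], dim[2]);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y,
                         Rcpp::List w0, Rcpp::IntegerMatrix orders,
                         int epochs, int batch_size, double lr,
                         double beta1, double beta2, double eps) {
  const Dims d = dims_from_array(x);
  Rcpp::IntegerVector dim = x.attr("dim");
  const int N = dim[3];
  if (y.size() != N) Rcpp::stop("label / image count mismatch");
  if (orders.nrow() != N || orders.ncol() != epochs)
    Rcpp::stop("orders must be N x epochs");

  Weights wt = weights_from_list(w0);
  if ((int)wt.W3.n_cols != d.D)
    Rcpp::stop("dense layer width does not match the input image size");
  Weights g;
  g.zeros_like(wt);
  Adam adam(wt);
  const int cap = std::min(batch_size, N);
  Workspace ws(d, cap);
  std::vector<double> loss_hist;
  loss_hist.reserve(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    int done = 0;
    while (done < N) {
      const int bn = std::min(batch_size, N - done);
      for (int b = 0; b < bn; ++b)
        load_image(x.begin(), d, orders(done + b, ep) - 1, ws.in, b);
      forward(wt, d, ws, bn);
      frowvec dz4(bn);
      for (int b = 0; b < bn; ++b) {
        const float yy = (float)y[orders(done + b, ep) - 1];
        const float oc = std::min(std::max(ws.o(b), 1e-7f), 1.0f - 1e-7f);
        ep_loss += -(yy * std::log(oc) + (1.0f - yy) * std::log(1.0f - oc));
        dz4(b) = (ws.o(b) - yy) / bn;
      }
      g.W1.zeros(); g.b1.zeros(); g.W2.zeros(); g.b2.zeros();
      g.W3.zeros(); g.b3.zeros(); g.W4.zeros(); g.b4.zeros();
      backward(wt, d, ws, bn, dz4, g);
      adam.step(wt, g, (float)lr, (float)beta1, (float)beta2, (float)eps);
      done += bn;
      Rcpp::checkUserInterrupt();
    }
    loss_hist.push_back(ep_loss / N);
  }

  Rcpp::List out = weights_to_list(wt);
  out["loss_history"] = loss_hist;
  return out;
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
Rcpp::NumericVector cnn_predict_cpp(Rcpp::NumericVector x, Rcpp::List w) {
  const Dims d = dims_from_array(x);
  Rcpp::IntegerVector dim = x.attr("dim");
  const int N = dim[3];
  Weights wt = weights_from_list(w);
  if ((int)wt.W3.n_cols != d.D)
    Rcpp::stop("image size does not match the trained model");
  const int cap = std::min(32, N);
  Workspace ws(d, cap);
  Rcpp::NumericVector out(N);
  int done = 0;
  while (done < N) {
    const int bn = std::min(cap, N - done);
    for (int b = 0; b < bn; ++b) load_image(x.begin(), d, done + b, ws.in, b);
    forward(wt, d, ws, bn);
    for (int b = 0; b < bn; ++b) out[done + b] = ws.o(b);
    done += bn;
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_flatten_width")]]
int cnn_flatten_width(int H, int W) {
  return make_dims(H, W, 3).D;
}
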