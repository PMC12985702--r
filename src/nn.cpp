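// Compact nested-skip convolutional encoder-decoder for binary segmentation.
// Layout: input HxWx3 (arma::cube, slices = channels), all convs 3x3 same
// padding, 2x average pooling / nearest upsampling, ReLU activations, a 1x1
// logit head. Two encoder levels plus a bottleneck; the top level has the
// dense intermediate node X(0,1) so the decoder sees both the raw encoder
// features and a refined skip, as in nested-skip (U-Net++-style) designs.
//
// Weight list (R side, named):
//   e0_W (27 x c0),  e1_W (9*c0 x c1),  bt_W (9*c1 x c2),
//   d1_W (9*(c1+c2) x c1), x01_W (9*(c0+c1) x c0),
//   d0_W (9*(2*c0+c1) x c0), hd_W (c0 x 1); *_b matching biases.
// Conv weight row order: offset k (dy,dx in row-major -1..1) major, input
// channel minor: row = k * Cin + c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const int OFF[9][2] = {{-1,-1},{-1,0},{-1,1},{0,-1},{0,0},{0,1},{1,-1},{1,0},{1,1}};

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * (size_t)W, 9 * (size_t)C, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int dy = OFF[k][0], dx = OFF[k][1];
    const int i0 = std::max(0, -dy), i1 = H - 1 - std::max(0, dy);
    const int j0 = std::max(0, -dx), j1 = W - 1 - std::max(0, dx);
    if (i0 > i1 || j0 > j1) continue;
    for (int c = 0; c < C; ++c) {
      mat sh(H, W, fill::zeros);
      sh.submat(i0, j0, i1, j1) =
        x.slice(c).submat(i0 + dy, j0 + dx, i1 + dy, j1 + dx);
      out.col((size_t)k * C + c) = vectorise(sh);
    }
  }
  return out;
}

static cube col2im3(const mat& dcols, int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int dy = OFF[k][0], dx_ = OFF[k][1];
    const int i0 = std::max(0, -dy), i1 = H - 1 - std::max(0, dy);
    const int j0 = std::max(0, -dx_), j1 = W - 1 - std::max(0, dx_);
    if (i0 > i1 || j0 > j1) continue;
    for (int c = 0; c < C; ++c) {
      mat sh = reshape(dcols.col((size_t)k * C + c), H, W);
      dx.slice(c).submat(i0 + dy, j0 + dx_, i1 + dy, j1 + dx_) +=
        sh.submat(i0, j0, i1, j1);
    }
  }
  return dx;
}

static cube mat2cube(const mat& m, int H, int W) {
  cube out(H, W, m.n_cols);
  for (uword c = 0; c < m.n_cols; ++c) out.slice(c) = reshape(m.col(c), H, W);
  return out;
}

static mat cube2mat(const cube& x) {
  mat out(x.n_rows * (size_t)x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) out.col(c) = vectorise(x.slice(c));
  return out;
}

static cube avgpool2(const cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2;
  cube out(H, W, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = 0.25 * (x(2*i, 2*j, c) + x(2*i+1, 2*j, c) +
                               x(2*i, 2*j+1, c) + x(2*i+1, 2*j+1, c));
  return out;
}

static cube avgpool2_back(const cube& d, int H, int W) {
  cube out(H, W, d.n_slices);
  for (uword c = 0; c < d.n_slices; ++c)
    for (uword j = 0; j < d.n_cols; ++j)
      for (uword i = 0; i < d.n_rows; ++i) {
        const double v = 0.25 * d(i, j, c);
        out(2*i, 2*j, c) = v; out(2*i+1, 2*j, c) = v;
        out(2*i, 2*j+1, c) = v; out(2*i+1, 2*j+1, c) = v;
      }
  return out;
}

static cube up2(const cube& x) {
  cube out(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        out(2*i, 2*j, c) = v; out(2*i+1, 2*j, c) = v;
        out(2*i, 2*j+1, c) = v; out(2*i+1, 2*j+1, c) = v;
      }
  return out;
}

static cube up2_back(const cube& d) {
  cube out(d.n_rows / 2, d.n_cols / 2, d.n_slices);
  for (uword c = 0; c < d.n_slices; ++c)
    for (uword j = 0; j < out.n_cols; ++j)
      for (uword i = 0; i < out.n_rows; ++i)
        out(i, j, c) = d(2*i, 2*j, c) + d(2*i+1, 2*j, c) +
                       d(2*i, 2*j+1, c) + d(2*i+1, 2*j+1, c);
  return out;
}

struct ConvCache { mat cols; cube act; };  // post-ReLU activation

static cube conv3_relu(const cube& x, const mat& W, const rowvec& b,
                       ConvCache& cc, bool want_grad) {
  mat cols = im2col3(x);
  mat y = cols * W;
  y.each_row() += b;
  y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  cube act = mat2cube(y, x.n_rows, x.n_cols);
  if (want_grad) { cc.cols = std::move(cols); cc.act = act; }
  return act;
}

// backward through ReLU + conv given upstream grad on the activation
static cube conv3_relu_back(const cube& dact, const ConvCache& cc,
                            const mat& W, mat& dW, rowvec& db,
                            int Hin, int Win, int Cin) {
  mat dy = cube2mat(dact);
  mat am = cube2mat(cc.act);
  dy %= conv_to<mat>::from(am > 0.0);
  dW = cc.cols.t() * dy;
  db = sum(dy, 0);
  mat dcols = dy * W.t();
  return col2im3(dcols, Hin, Win, Cin);
}

struct Net {
  mat e0_W, e1_W, bt_W, d1_W, x01_W, d0_W, hd_W;
  rowvec e0_b, e1_b, bt_b, d1_b, x01_b, d0_b;
  double hd_b;
};

static Net unpack(const List& w) {
  Net n;
  n.e0_W = as<mat>(w["e0_W"]);  n.e0_b = as<rowvec>(w["e0_b"]);
  n.e1_W = as<mat>(w["e1_W"]);  n.e1_b = as<rowvec>(w["e1_b"]);
  n.bt_W = as<mat>(w["bt_W"]);  n.bt_b = as<rowvec>(w["bt_b"]);
  n.d1_W = as<mat>(w["d1_W"]);  n.d1_b = as<rowvec>(w["d1_b"]);
  n.x01_W = as<mat>(w["x01_W"]); n.x01_b = as<rowvec>(w["x01_b"]);
  n.d0_W = as<mat>(w["d0_W"]);  n.d0_b = as<rowvec>(w["d0_b"]);
  n.hd_W = as<mat>(w["hd_W"]);  n.hd_b = as<NumericVector>(w["hd_b"])[0];
  return n;
}

struct Caches {
  ConvCache e0, e1, bt, d1, x01, d0;
  cube a0, a1, d1a;
  mat d0m;
};

static mat forward(const Net& n, const cube& x, Caches& cc, bool want_grad) {
  const int H = x.n_rows, W = x.n_cols;
  cube a0 = conv3_relu(x, n.e0_W, n.e0_b, cc.e0, want_grad);
  cube p0 = avgpool2(a0);
  cube a1 = conv3_relu(p0, n.e1_W, n.e1_b, cc.e1, want_grad);
  cube p1 = avgpool2(a1);
  cube a2 = conv3_relu(p1, n.bt_W, n.bt_b, cc.bt, want_grad);
  cube cat1 = join_slices(a1, up2(a2));
  cube d1 = conv3_relu(cat1, n.d1_W, n.d1_b, cc.d1, want_grad);
  cube cat01 = join_slices(a0, up2(a1));
  cube x01 = conv3_relu(cat01, n.x01_W, n.x01_b, cc.x01, want_grad);
  cube cat0 = join_slices(join_slices(a0, x01), up2(d1));
  cube d0 = conv3_relu(cat0, n.d0_W, n.d0_b, cc.d0, want_grad);
  mat d0m = cube2mat(d0);
  mat z = d0m * n.hd_W;
  z += n.hd_b;
  if (want_grad) { cc.a0 = a0; cc.a1 = a1; cc.d1a = d1; cc.d0m = d0m; }
  return reshape(z, H, W);
}

// [[Rcpp::export(name = ".nn_forward_cpp")]]
NumericMatrix nn_forward_cpp(List weights, arma::cube x) {
  Net n = unpack(weights);
  Caches cc;
  mat z = forward(n, x, cc, false);
  return wrap(z);
}

// [[Rcpp::export(name = ".nn_grad_cpp")]]
List nn_grad_cpp(List weights, arma::cube x, arma::mat target) {
  Net n = unpack(weights);
  Caches cc;
  const int H = x.n_rows, W = x.n_cols;
  const int c0 = n.e0_W.n_cols, c1 = n.e1_W.n_cols, c2 = n.bt_W.n_cols;
  mat z = forward(n, x, cc, true);

  // stable BCE with logits, mean over pixels
  mat az = abs(z);
  double loss = accu(clamp(z, 0.0, datum::inf) - z % target +
                     log1p(exp(-az))) / (H * (double)W);
  mat p = 1.0 / (1.0 + exp(-z));
  vec dz = vectorise((p - target) / (H * (double)W));

  mat dhd_W = cc.d0m.t() * dz;
  double dhd_b = accu(dz);
  mat dd0m = dz * n.hd_W.t();
  cube dd0 = mat2cube(dd0m, H, W);

  mat d0_dW, x01_dW, d1_dW, bt_dW, e1_dW, e0_dW;
  rowvec d0_db, x01_db, d1_db, bt_db, e1_db, e0_db;

  cube dcat0 = conv3_relu_back(dd0, cc.d0, n.d0_W, d0_dW, d0_db,
                               H, W, 2 * c0 + c1);
  cube da0 = dcat0.slices(0, c0 - 1);
  cube dx01 = dcat0.slices(c0, 2 * c0 - 1);
  cube dd1 = up2_back(dcat0.slices(2 * c0, 2 * c0 + c1 - 1));

  cube dcat01 = conv3_relu_back(dx01, cc.x01, n.x01_W, x01_dW, x01_db,
                                H, W, c0 + c1);
  da0 += dcat01.slices(0, c0 - 1);
  cube da1 = up2_back(dcat01.slices(c0, c0 + c1 - 1));

  cube dcat1 = conv3_relu_back(dd1, cc.d1, n.d1_W, d1_dW, d1_db,
                               H / 2, W / 2, c1 + c2);
  da1 += dcat1.slices(0, c1 - 1);
  cube da2 = up2_back(dcat1.slices(c1, c1 + c2 - 1));

  cube dp1 = conv3_relu_back(da2, cc.bt, n.bt_W, bt_dW, bt_db,
                             H / 4, W / 4, c1);
  da1 += avgpool2_back(dp1, H / 2, W / 2);

  cube dp0 = conv3_relu_back(da1, cc.e1, n.e1_W, e1_dW, e1_db,
                             H / 2, W / 2, c0);
  da0 += avgpool2_back(dp0, H, W);

  conv3_relu_back(da0, cc.e0, n.e0_W, e0_dW, e0_db, H, W, 3);

  return List::create(
    _["loss"] = loss,
    _["grads"] = List::create(
      _["e0_W"] = e0_dW, _["e0_b"] = e0_db,
      _["e1_W"] = e1_dW, _["e1_b"] = e1_db,
      _["bt_W"] = bt_dW, _["bt_b"] = bt_db,
      _["d1_W"] = d1_dW, _["d1_b"] = d1_db,
      _["x01_W"] = x01_dW, _["x01_b"] = x01_db,
      _["d0_W"] = d0_dW, _["d0_b"] = d0_db,
      _["hd_W"] = dhd_W, _["hd_b"] = dhd_b));
}
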