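// CNN-LSTM component forecaster: forward pass, backpropagation through
// time and Adam updates, batched with Armadillo.  The network is
//   conv1d (valid, ReLU) -> non-overlapping max pool -> LSTM -> dense(1)
// and the LSTM gates follow
//   i = sigmoid(Wxi x + Whi h + bi)
//   f = sigmoid(Wxf x + Whf h + bf)
//   c = f . c_prev + i . tanh(Wxc x + Whc h + bc)
//   o = sigmoid(Wxo x + Who h + Wco c + bo)
//   h = o . tanh(c)
// (peephole Wco on the output gate; biases on every gate).
//
// External parameter layout (see model_weights() in R/cnnlstm.R):
//   Wc (k*C x F) conv kernels, column (a + c*k) = window row a, channel c
//   bc (1 x F); Wxi Wxf Wxc Wxo (F x m); Whi Whf Whc Who (m x m);
//   Wco (m x m); bi bf bg bo (1 x m); wd (m x 1); bd (1 x 1).
//
// Internally the four gates are fused into single matrices
// (Wx: F x 4m, Wh: m x 4m, b: 1 x 4m, gate order i|f|g|o) so each
// timestep costs two GEMMs instead of eight.  Training runs in single
// precision (GEMM-bound; the stochastic gradient noise dwarfs float
// rounding), weights are stored and inference is computed in double so
// forward passes agree with the R operator composition to full
// precision.

#include <RcppArmadillo.h>
#include <algorithm>
#include <cmath>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

template <typename eT>
struct Net {
  Mat<eT> Wc, bc;        // conv
  Mat<eT> Wx, Wh, Wco;   // fused LSTM weights
  Mat<eT> b;             // fused gate biases (1 x 4m)
  Mat<eT> wd, bd;        // dense head
  int k = 2, C = 1, F = 16, m = 8, pool = 1;
};

template <typename eT>
std::vector<Mat<eT>*> param_ptrs(Net<eT>& n) {
  return {&n.Wc, &n.bc, &n.Wx, &n.Wh, &n.Wco, &n.b, &n.wd, &n.bd};
}

template <typename eT>
Net<eT> from_list(const Rcpp::List& par) {
  Net<double> n;
  Rcpp::List dims = par["dims"];
  n.k = dims["kernel_size"];
  n.C = dims["channels"];
  n.F = dims["filters"];
  n.m = dims["cells"];
  n.pool = dims["pool_size"];
  Rcpp::List w = par["weights"];
  n.Wc = Rcpp::as<mat>(w["Wc"]);
  n.bc = Rcpp::as<mat>(w["bc"]);
  n.Wx = join_horiz(join_horiz(Rcpp::as<mat>(w["Wxi"]), Rcpp::as<mat>(w["Wxf"])),
                    join_horiz(Rcpp::as<mat>(w["Wxc"]), Rcpp::as<mat>(w["Wxo"])));
  n.Wh = join_horiz(join_horiz(Rcpp::as<mat>(w["Whi"]), Rcpp::as<mat>(w["Whf"])),
                    join_horiz(Rcpp::as<mat>(w["Whc"]), Rcpp::as<mat>(w["Who"])));
  n.Wco = Rcpp::as<mat>(w["Wco"]);
  n.b = join_horiz(join_horiz(Rcpp::as<mat>(w["bi"]), Rcpp::as<mat>(w["bf"])),
                   join_horiz(Rcpp::as<mat>(w["bg"]), Rcpp::as<mat>(w["bo"])));
  n.wd = Rcpp::as<mat>(w["wd"]);
  n.bd = Rcpp::as<mat>(w["bd"]);
  Net<eT> out;
  out.k = n.k; out.C = n.C; out.F = n.F; out.m = n.m; out.pool = n.pool;
  auto src = param_ptrs(n);
  auto dst = param_ptrs(out);
  for (size_t i = 0; i < src.size(); ++i) {
    *dst[i] = conv_to<Mat<eT>>::from(*src[i]);
  }
  return out;
}

template <typename eT>
Rcpp::List to_list(const Net<eT>& nn) {
  Net<double> n;
  n.k = nn.k; n.C = nn.C; n.F = nn.F; n.m = nn.m; n.pool = nn.pool;
  {
    Net<eT>& mut = const_cast<Net<eT>&>(nn);
    auto src = param_ptrs(mut);
    auto dst = param_ptrs(n);
    for (size_t i = 0; i < src.size(); ++i) {
      *dst[i] = conv_to<mat>::from(*src[i]);
    }
  }
  const int m = n.m;
  Rcpp::List w;
  w["Wc"] = n.Wc;
  w["bc"] = n.bc;
  w["Wxi"] = mat(n.Wx.cols(0, m - 1));
  w["Wxf"] = mat(n.Wx.cols(m, 2 * m - 1));
  w["Wxc"] = mat(n.Wx.cols(2 * m, 3 * m - 1));
  w["Wxo"] = mat(n.Wx.cols(3 * m, 4 * m - 1));
  w["Whi"] = mat(n.Wh.cols(0, m - 1));
  w["Whf"] = mat(n.Wh.cols(m, 2 * m - 1));
  w["Whc"] = mat(n.Wh.cols(2 * m, 3 * m - 1));
  w["Who"] = mat(n.Wh.cols(3 * m, 4 * m - 1));
  w["Wco"] = n.Wco;
  w["bi"] = mat(n.b.cols(0, m - 1));
  w["bf"] = mat(n.b.cols(m, 2 * m - 1));
  w["bg"] = mat(n.b.cols(2 * m, 3 * m - 1));
  w["bo"] = mat(n.b.cols(3 * m, 4 * m - 1));
  w["wd"] = n.wd;
  w["bd"] = n.bd;
  return Rcpp::List::create(
    Rcpp::Named("dims") = Rcpp::List::create(
      Rcpp::Named("kernel_size") = n.k, Rcpp::Named("channels") = n.C,
      Rcpp::Named("filters") = n.F, Rcpp::Named("cells") = n.m,
      Rcpp::Named("pool_size") = n.pool),
    Rcpp::Named("weights") = w);
}

template <typename eT>
inline Mat<eT> sigmoid(const Mat<eT>& z) {
  return eT(1) / (eT(1) + exp(-z));
}

// Flattened conv input for output position t (0-based): B x (k*C)
template <typename eT>
Mat<eT> conv_window(const Cube<eT>& X, const uvec& rows, int t, int k) {
  const int C = X.n_slices;
  Mat<eT> out(rows.n_elem, k * C);
  for (int c = 0; c < C; ++c) {
    for (int a = 0; a < k; ++a) {
      Col<eT> col = X.slice(c).col(t + a);
      out.col(a + c * k) = col.elem(rows);
    }
  }
  return out;
}

template <typename eT>
struct ForwardCache {
  std::vector<Mat<eT>> Xflat;          // per conv position: B x kC
  std::vector<Mat<eT>> convZ, convA;   // per conv position: B x F
  std::vector<umat> poolArg;           // per pooled position: conv index
  std::vector<Mat<eT>> Xp;             // per pooled position: B x F
  std::vector<Mat<eT>> I, Fg, G, O, Cs, Hs;  // per LSTM step: B x m
  Col<eT> yhat;
};

// Forward through the whole network for the sample rows `rows` of X.
template <typename eT>
ForwardCache<eT> forward(const Net<eT>& n, const Cube<eT>& X,
                         const uvec& rows, bool keep = true) {
  const int B = rows.n_elem;
  const int win = X.n_cols;
  const int Lc = win - n.k + 1;
  const int Lp = (Lc + n.pool - 1) / n.pool;
  const int m = n.m;
  ForwardCache<eT> fc;
  fc.convA.resize(Lc);
  if (keep) { fc.Xflat.resize(Lc); fc.convZ.resize(Lc); }
  for (int t = 0; t < Lc; ++t) {
    Mat<eT> xf = conv_window(X, rows, t, n.k);
    Mat<eT> z = xf * n.Wc;
    z.each_row() += n.bc;
    fc.convA[t] = clamp(z, eT(0), std::numeric_limits<eT>::max());  // ReLU
    if (keep) { fc.Xflat[t] = std::move(xf); fc.convZ[t] = std::move(z); }
  }
  fc.Xp.resize(Lp);
  fc.poolArg.resize(Lp);
  for (int p = 0; p < Lp; ++p) {
    int lo = p * n.pool;
    int hi = std::min(lo + n.pool, Lc) - 1;
    Mat<eT> best = fc.convA[lo];
    umat arg(B, n.F);
    arg.fill(lo);
    for (int t = lo + 1; t <= hi; ++t) {
      umat upd = fc.convA[t] > best;
      best = max(best, fc.convA[t]);
      arg.elem(find(upd)).fill(t);
    }
    fc.Xp[p] = std::move(best);
    fc.poolArg[p] = std::move(arg);
  }
  Mat<eT> H(B, m, fill::zeros), Cst(B, m, fill::zeros);
  fc.I.resize(Lp); fc.Fg.resize(Lp); fc.G.resize(Lp);
  fc.O.resize(Lp); fc.Cs.resize(Lp); fc.Hs.resize(Lp);
  for (int p = 0; p < Lp; ++p) {
    Mat<eT> Z = fc.Xp[p] * n.Wx + H * n.Wh;   // B x 4m, gates i|f|g|o
    Z.each_row() += n.b;
    Mat<eT> I = sigmoid<eT>(Z.cols(0, m - 1));
    Mat<eT> Fg = sigmoid<eT>(Z.cols(m, 2 * m - 1));
    Mat<eT> G = tanh(Z.cols(2 * m, 3 * m - 1));
    Mat<eT> Cnew = Fg % Cst + I % G;
    Mat<eT> O = sigmoid<eT>(Mat<eT>(Z.cols(3 * m, 4 * m - 1) + Cnew * n.Wco));
    Mat<eT> Hnew = O % tanh(Cnew);
    fc.I[p] = std::move(I); fc.Fg[p] = std::move(Fg); fc.G[p] = std::move(G);
    fc.O[p] = std::move(O); fc.Cs[p] = Cnew; fc.Hs[p] = Hnew;
    H = std::move(Hnew);
    Cst = std::move(Cnew);
  }
  fc.yhat = H * n.wd + as_scalar(n.bd);
  return fc;
}

// Gradients of mean squared error over the minibatch; fused layout.
template <typename eT>
std::vector<Mat<eT>> backward(const Net<eT>& n, const uvec& rows,
                              const Col<eT>& y, const ForwardCache<eT>& fc) {
  const int B = rows.n_elem;
  const int Lc = fc.convA.size();
  const int Lp = fc.Xp.size();
  const int m = n.m;

  Net<eT> g;
  g.Wc = zeros<Mat<eT>>(size(n.Wc)); g.bc = zeros<Mat<eT>>(size(n.bc));
  g.Wx = zeros<Mat<eT>>(size(n.Wx)); g.Wh = zeros<Mat<eT>>(size(n.Wh));
  g.Wco = zeros<Mat<eT>>(size(n.Wco)); g.b = zeros<Mat<eT>>(size(n.b));
  g.wd = zeros<Mat<eT>>(size(n.wd)); g.bd = zeros<Mat<eT>>(size(n.bd));

  Col<eT> dy = eT(2) * (fc.yhat - y) / eT(B);
  g.wd = fc.Hs[Lp - 1].t() * dy;
  g.bd(0, 0) = accu(dy);

  Mat<eT> dH = dy * n.wd.t();           // B x m
  Mat<eT> dC(B, m, fill::zeros);
  std::vector<Mat<eT>> dXp(Lp);
  for (int p = Lp - 1; p >= 0; --p) {
    const Mat<eT>& Ct = fc.Cs[p];
    const Mat<eT>& O = fc.O[p];
    const Mat<eT>& I = fc.I[p];
    const Mat<eT>& Fg = fc.Fg[p];
    const Mat<eT>& G = fc.G[p];
    Mat<eT> tC = tanh(Ct);
    Mat<eT> dzo = (dH % tC) % O % (eT(1) - O);
    Mat<eT> dc = dH % O % (eT(1) - tC % tC) + dC + dzo * n.Wco.t();
    Mat<eT> Cprev = (p == 0) ? Mat<eT>(B, m, fill::zeros) : fc.Cs[p - 1];
    Mat<eT> Hprev = (p == 0) ? Mat<eT>(B, m, fill::zeros) : fc.Hs[p - 1];
    Mat<eT> dZ(B, 4 * m);
    dZ.cols(0, m - 1) = (dc % G) % I % (eT(1) - I);
    dZ.cols(m, 2 * m - 1) = (dc % Cprev) % Fg % (eT(1) - Fg);
    dZ.cols(2 * m, 3 * m - 1) = (dc % I) % (eT(1) - G % G);
    dZ.cols(3 * m, 4 * m - 1) = dzo;
    dC = dc % Fg;
    g.Wx += fc.Xp[p].t() * dZ;
    g.Wh += Hprev.t() * dZ;
    g.Wco += Ct.t() * dzo;
    g.b += sum(dZ, 0);
    dXp[p] = dZ * n.Wx.t();
    dH = dZ * n.Wh.t();
  }

  // pool + ReLU + conv backward
  std::vector<Mat<eT>> dConv(Lc, Mat<eT>(B, n.F, fill::zeros));
  for (int p = 0; p < Lp; ++p) {
    const umat& arg = fc.poolArg[p];
    const Mat<eT>& d = dXp[p];
    for (int f = 0; f < n.F; ++f) {
      for (int b2 = 0; b2 < B; ++b2) {
        dConv[arg(b2, f)](b2, f) += d(b2, f);
      }
    }
  }
  for (int t = 0; t < Lc; ++t) {
    Mat<eT> mask = conv_to<Mat<eT>>::from(fc.convZ[t] > eT(0));
    Mat<eT> dz = dConv[t] % mask;
    g.Wc += fc.Xflat[t].t() * dz;
    g.bc += sum(dz, 0);
  }

  std::vector<Mat<eT>> out;
  auto ptrs = param_ptrs(g);
  for (auto* p : ptrs) out.push_back(*p);
  return out;
}

double glorot_limit(int fan_in, int fan_out) {
  return std::sqrt(6.0 / (fan_in + fan_out));
}

mat init_mat(int r, int c, double lim, std::mt19937& rng) {
  std::uniform_real_distribution<double> u(-lim, lim);
  mat out(r, c);
  for (uword j = 0; j < out.n_cols; ++j) {
    for (uword i = 0; i < out.n_rows; ++i) out(i, j) = u(rng);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnnlstm_init_cpp(int kernel_size, int channels, int filters,
                            int cells, int pool_size, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  Net<double> n;
  n.k = kernel_size; n.C = channels; n.F = filters; n.m = cells;
  n.pool = pool_size;
  const int kc = kernel_size * channels;
  n.Wc = init_mat(kc, filters, glorot_limit(kc, filters), rng);
  n.bc = zeros(1, filters);
  double lx = glorot_limit(filters + cells, cells);
  // draw gate-by-gate in a fixed order so results are reproducible
  mat Wxi = init_mat(filters, cells, lx, rng);
  mat Wxf = init_mat(filters, cells, lx, rng);
  mat Wxc = init_mat(filters, cells, lx, rng);
  mat Wxo = init_mat(filters, cells, lx, rng);
  mat Whi = init_mat(cells, cells, lx, rng);
  mat Whf = init_mat(cells, cells, lx, rng);
  mat Whc = init_mat(cells, cells, lx, rng);
  mat Who = init_mat(cells, cells, lx, rng);
  n.Wx = join_horiz(join_horiz(Wxi, Wxf), join_horiz(Wxc, Wxo));
  n.Wh = join_horiz(join_horiz(Whi, Whf), join_horiz(Whc, Who));
  n.Wco = init_mat(cells, cells, lx, rng);
  n.b = join_horiz(join_horiz(zeros(1, cells), ones(1, cells)),
                   zeros(1, 2 * cells));  // open forget gate at start
  n.wd = init_mat(cells, 1, glorot_limit(cells, 1), rng);
  n.bd = zeros(1, 1);
  return to_list(n);
}

// [[Rcpp::export]]
Rcpp::List cnnlstm_fit_cpp(const arma::cube& X, const arma::vec& y,
                           Rcpp::List par, int epochs, int batch_size,
                           double learning_rate, int seed,
                           SEXP X_val = R_NilValue,
                           SEXP y_val = R_NilValue) {
  typedef float eT;
  Net<eT> n = from_list<eT>(par);
  const int S = X.n_rows;
  if (batch_size < 1) batch_size = 1;
  if (batch_size > S) batch_size = S;
  std::mt19937 rng(static_cast<unsigned>(seed) + 1000003u);

  Cube<eT> Xf = conv_to<Cube<eT>>::from(X);
  Col<eT> yf = conv_to<Col<eT>>::from(y);

  auto ptrs = param_ptrs(n);
  std::vector<Mat<eT>> mAdam, vAdam;
  for (auto* p : ptrs) {
    mAdam.push_back(zeros<Mat<eT>>(size(*p)));
    vAdam.push_back(zeros<Mat<eT>>(size(*p)));
  }
  const double b1 = 0.9, b2 = 0.999;
  const eT eps = eT(1e-7);
  long step = 0;

  bool has_val = !Rf_isNull(X_val) && !Rf_isNull(y_val);
  Cube<eT> Xv;
  Col<eT> yv;
  if (has_val) {
    Xv = conv_to<Cube<eT>>::from(Rcpp::as<cube>(X_val));
    yv = conv_to<Col<eT>>::from(Rcpp::as<vec>(y_val));
  }

  vec train_loss(epochs, fill::zeros), val_loss(epochs, fill::zeros);
  std::vector<unsigned> order(S);
  for (int i = 0; i < S; ++i) order[i] = i;

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double sse = 0;
    for (int start = 0; start < S; start += batch_size) {
      int end = std::min(start + batch_size, S);
      uvec rows(end - start);
      for (int i = start; i < end; ++i) rows[i - start] = order[i];
      Col<eT> yb = yf.elem(rows);
      ForwardCache<eT> fc = forward<eT>(n, Xf, rows, true);
      sse += accu(square(conv_to<vec>::from(fc.yhat - yb)));
      std::vector<Mat<eT>> grads = backward<eT>(n, rows, yb, fc);
      ++step;
      eT corr = eT(learning_rate * std::sqrt(1.0 - std::pow(b2, step)) /
                   (1.0 - std::pow(b1, step)));
      for (size_t i = 0; i < ptrs.size(); ++i) {
        mAdam[i] = eT(b1) * mAdam[i] + eT(1 - b1) * grads[i];
        vAdam[i] = eT(b2) * vAdam[i] + eT(1 - b2) * square(grads[i]);
        *ptrs[i] -= corr * mAdam[i] / (sqrt(vAdam[i]) + eps);
      }
    }
    train_loss[e] = sse / S;
    if (!std::isfinite(train_loss[e])) {
      Rcpp::stop("training loss became non-finite at epoch %d; "
                 "try a smaller learning rate", e + 1);
    }
    if (has_val) {
      uvec vr = regspace<uvec>(0, Xv.n_rows - 1);
      ForwardCache<eT> fv = forward<eT>(n, Xv, vr, false);
      val_loss[e] = accu(square(conv_to<vec>::from(fv.yhat - yv))) / yv.n_elem;
    }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List out = to_list(n);
  out["train_loss"] = train_loss;
  if (has_val) out["val_loss"] = val_loss;
  return out;
}

// [[Rcpp::export]]
arma::vec cnnlstm_predict_cpp(const arma::cube& X, Rcpp::List par) {
  Net<double> n = from_list<double>(par);
  uvec rows = regspace<uvec>(0, X.n_rows - 1);
  ForwardCache<double> fc = forward<double>(n, X, rows, false);
  return fc.yhat;
}
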