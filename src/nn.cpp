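// Hybrid CNN / bi-LSTM binary sequence classifier: forward pass, exact
// backprop and an eval-mode forward. Batches are cubes (len x dim x n).
// Gate block order inside stacked LSTM matrices is (f, i, g, o).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;

struct NetConfig {
  int nConv;      // number of conv modules (0 for rnn_only)
  int C;          // conv channels per module
  int k;          // conv kernel size (odd; zero-padded "same")
  int pool;       // max-pool window == stride
  int H;          // LSTM units per direction (0 for cnn_only)
  int fcHidden;   // first FC layer width
  bool batchNorm;
  int arch;       // 0 hybrid, 1 cnn_only, 2 rnn_only
  int rnnHead;    // 0 flatten all positions, 1 max over time
};

static NetConfig parseConfig(const List& cfg) {
  NetConfig c;
  std::string a = as<std::string>(cfg["arch"]);
  c.arch = (a == "hybrid") ? 0 : (a == "cnn_only" ? 1 : 2);
  c.nConv = (c.arch == 2) ? 0 : as<int>(cfg["nConv"]);
  c.C = as<int>(cfg["convChannels"]);
  c.k = as<int>(cfg["kernelSize"]);
  c.pool = as<int>(cfg["poolWindow"]);
  c.H = (c.arch == 1) ? 0 : as<int>(cfg["lstmUnits"]);
  c.fcHidden = as<int>(cfg["fcHidden"]);
  c.batchNorm = as<bool>(cfg["batchNorm"]);
  std::string h = as<std::string>(cfg["rnnHead"]);
  c.rnnHead = (h == "maxpool") ? 1 : 0;
  return c;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static cube relu_c(const cube& Z) {
  cube R = Z;
  R.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return R;
}
static mat relu_m(const mat& Z) {
  mat R = Z;
  R.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return R;
}

// ---------------------------------------------------------------- conv utils

// Weight layout: W is (Cout x Cin*k), column c*k + j = channel c, offset j.
// The convolution is computed as k shifted matrix products per record
// (no im2col materialisation): Y.rows(t0,t1) += X.rows(src range) * Wj^T.
static std::vector<mat> splitKernel(const mat& W, int k) {
  const int Cout = W.n_rows, Cin = W.n_cols / k;
  std::vector<mat> Wj(k, mat(Cout, Cin));
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < Cin; ++c)
      Wj[j].col(c) = W.col(c * k + j);
  return Wj;
}

static cube conv_forward(const cube& X, const mat& W, const vec& b, int k) {
  const int pad = (k - 1) / 2;
  const int L = X.n_rows, n = X.n_slices, Cout = W.n_rows;
  std::vector<mat> Wj = splitKernel(W, k);
  std::vector<mat> WjT(k);
  for (int j = 0; j < k; ++j) WjT[j] = Wj[j].t();
  cube Y(L, Cout, n);
  for (int s = 0; s < n; ++s) {
    mat& Ys = Y.slice(s);
    Ys.each_row() = b.t();
    for (int j = 0; j < k; ++j) {
      const int t0 = std::max(0, pad - j);
      const int t1 = std::min(L - 1, L - 1 + pad - j);
      if (t0 > t1) continue;
      Ys.rows(t0, t1) += X.slice(s).rows(t0 - pad + j, t1 - pad + j) * WjT[j];
    }
  }
  return Y;
}

static cube conv_backward(const cube& X, const mat& W, const cube& dY,
                          int k, mat& dW, vec& db) {
  const int pad = (k - 1) / 2;
  const int L = X.n_rows, n = X.n_slices, Cout = W.n_rows;
  const int Cin = W.n_cols / k;
  std::vector<mat> Wj = splitKernel(W, k);
  std::vector<mat> dWj(k, mat(Cout, Cin, fill::zeros));
  db.zeros(Cout);
  cube dX(size(X), fill::zeros);
  for (int s = 0; s < n; ++s) {
    const mat& dYs = dY.slice(s);
    db += sum(dYs, 0).t();
    for (int j = 0; j < k; ++j) {
      const int t0 = std::max(0, pad - j);
      const int t1 = std::min(L - 1, L - 1 + pad - j);
      if (t0 > t1) continue;
      dWj[j] += dYs.rows(t0, t1).t() * X.slice(s).rows(t0 - pad + j, t1 - pad + j);
      dX.slice(s).rows(t0 - pad + j, t1 - pad + j) += dYs.rows(t0, t1) * Wj[j];
    }
  }
  dW.set_size(Cout, Cin * k);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < Cin; ++c)
      dW.col(c * k + j) = dWj[j].col(c);
  return dX;
}

// ------------------------------------------------------------ batch norm

// Per-channel normalisation over (length x batch). Returns xhat for backprop.
static cube bn_forward_train(const cube& Z, const vec& gamma, const vec& beta,
                             vec& mu, vec& varb, cube& xhat) {
  const int L = Z.n_rows, C = Z.n_cols, n = Z.n_slices;
  const double m = (double)L * n;
  mu.zeros(C); varb.zeros(C);
  cube Y(size(Z));
  xhat.set_size(size(Z));
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += accu(Z.slice(j).col(c));
    mu(c) = s / m;
    double v = 0.0;
    for (int j = 0; j < n; ++j) v += accu(square(Z.slice(j).col(c) - mu(c)));
    varb(c) = v / m;
    const double inv = 1.0 / std::sqrt(varb(c) + BN_EPS);
    for (int j = 0; j < n; ++j) {
      vec xh = (Z.slice(j).col(c) - mu(c)) * inv;
      xhat.slice(j).col(c) = xh;
      Y.slice(j).col(c) = gamma(c) * xh + beta(c);
    }
  }
  return Y;
}

static cube bn_forward_eval(const cube& Z, const vec& gamma, const vec& beta,
                            const vec& rmean, const vec& rvar) {
  const int C = Z.n_cols, n = Z.n_slices;
  cube Y(size(Z));
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(rvar(c) + BN_EPS);
    for (int j = 0; j < n; ++j)
      Y.slice(j).col(c) = gamma(c) * (Z.slice(j).col(c) - rmean(c)) * inv + beta(c);
  }
  return Y;
}

static cube bn_backward(const cube& dY, const cube& xhat, const vec& gamma,
                        const vec& varb, vec& dgamma, vec& dbeta) {
  const int C = dY.n_cols, n = dY.n_slices, L = dY.n_rows;
  const double m = (double)L * n;
  dgamma.zeros(C); dbeta.zeros(C);
  cube dX(size(dY));
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(varb(c) + BN_EPS);
    double sdy = 0.0, sdyx = 0.0;
    for (int j = 0; j < n; ++j) {
      sdy += accu(dY.slice(j).col(c));
      sdyx += accu(dY.slice(j).col(c) % xhat.slice(j).col(c));
    }
    dgamma(c) = sdyx;
    dbeta(c) = sdy;
    for (int j = 0; j < n; ++j) {
      vec dxh = gamma(c) * dY.slice(j).col(c);
      dX.slice(j).col(c) =
        inv * (dxh - (gamma(c) * sdy) / m - xhat.slice(j).col(c) * (gamma(c) * sdyx) / m);
    }
  }
  return dX;
}

// ------------------------------------------------------------ max pooling

static cube pool_forward(const cube& X, int w, Cube<uword>& idx) {
  const int L = X.n_rows, C = X.n_cols, n = X.n_slices;
  const int L2 = L / w;
  cube Y(L2, C, n);
  idx.set_size(L2, C, n);
  for (int s = 0; s < n; ++s)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < L2; ++t) {
        uword best = (uword)(t * w);
        double bv = X(best, c, s);
        for (int j = 1; j < w; ++j) {
          const uword p = t * w + j;
          if (X(p, c, s) > bv) { bv = X(p, c, s); best = p; }
        }
        Y(t, c, s) = bv;
        idx(t, c, s) = best;
      }
  return Y;
}

static cube pool_backward(const cube& dY, const Cube<uword>& idx, int L) {
  const int L2 = dY.n_rows, C = dY.n_cols, n = dY.n_slices;
  cube dX(L, C, n, fill::zeros);
  for (int s = 0; s < n; ++s)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < L2; ++t)
        dX(idx(t, c, s), c, s) += dY(t, c, s);
  return dX;
}

// ---------------------------------------------------------------- LSTM

struct LSTMCache {
  cube F, I, G, O, Cc, Hs;   // each (H x n x L) in processing order
};

static mat timeslice(const cube& X, int t) {
  const int Cin = X.n_cols, n = X.n_slices;
  mat Xt(Cin, n);
  for (int j = 0; j < n; ++j) Xt.col(j) = X.slice(j).row(t).t();
  return Xt;
}

// One direction over the full sequence; returns the final hidden state.
static mat lstm_forward(const cube& X, const mat& W, const mat& U,
                        const vec& b, bool reverse, LSTMCache& cc) {
  const int L = X.n_rows, n = X.n_slices;
  const int H = U.n_rows / 4;
  cc.F.set_size(H, n, L); cc.I.set_size(H, n, L); cc.G.set_size(H, n, L);
  cc.O.set_size(H, n, L); cc.Cc.set_size(H, n, L); cc.Hs.set_size(H, n, L);
  mat h(H, n, fill::zeros), c(H, n, fill::zeros);
  for (int s = 0; s < L; ++s) {
    const int t = reverse ? (L - 1 - s) : s;
    mat pre = W * timeslice(X, t) + U * h;
    pre.each_col() += b;
    mat f = sigm(pre.rows(0, H - 1));
    mat i = sigm(pre.rows(H, 2 * H - 1));
    mat g = tanh(pre.rows(2 * H, 3 * H - 1));
    mat o = sigm(pre.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    cc.F.slice(s) = f; cc.I.slice(s) = i; cc.G.slice(s) = g;
    cc.O.slice(s) = o; cc.Cc.slice(s) = c; cc.Hs.slice(s) = h;
  }
  return h;
}

// Backprop through time given the gradient at the final hidden state only.
// dHext holds the gradient arriving at every hidden state from the head
// (slices in processing order).
static void lstm_backward(const cube& X, const mat& W, const mat& U,
                          bool reverse, const LSTMCache& cc, const cube& dHext,
                          mat& dW, mat& dU, vec& db, cube& dX) {
  const int L = X.n_rows, n = X.n_slices;
  const int H = U.n_rows / 4;
  dW.zeros(size(W)); dU.zeros(size(U)); db.zeros(4 * H);
  mat dh(H, n, fill::zeros), dc(H, n, fill::zeros);
  for (int s = L - 1; s >= 0; --s) {
    const int t = reverse ? (L - 1 - s) : s;
    dh += dHext.slice(s);
    const mat& f = cc.F.slice(s);
    const mat& i = cc.I.slice(s);
    const mat& g = cc.G.slice(s);
    const mat& o = cc.O.slice(s);
    const mat& c = cc.Cc.slice(s);
    mat cprev = (s > 0) ? cc.Cc.slice(s - 1) : mat(H, n, fill::zeros);
    mat tc = tanh(c);
    mat do_ = dh % tc;
    dc += dh % o % (1.0 - square(tc));
    mat df = dc % cprev;
    mat di = dc % g;
    mat dg = dc % i;
    mat dcprev = dc % f;
    mat dG(4 * H, n);
    dG.rows(0, H - 1)         = df % f % (1.0 - f);
    dG.rows(H, 2 * H - 1)     = di % i % (1.0 - i);
    dG.rows(2 * H, 3 * H - 1) = dg % (1.0 - square(g));
    dG.rows(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    mat Xt = timeslice(X, t);
    dW += dG * Xt.t();
    db += sum(dG, 1);
    mat hprev = (s > 0) ? cc.Hs.slice(s - 1) : mat(H, n, fill::zeros);
    dU += dG * hprev.t();
    mat dXt = W.t() * dG;                   // (Cin x n)
    for (int j = 0; j < n; ++j) dX.slice(j).row(t) += dXt.col(j).t();
    dh = U.t() * dG;
    dc = dcprev;
  }
}

// ---------------------------------------------------------------- helpers

static mat getM(const List& p, const std::string& nm) { return as<mat>(p[nm]); }
static vec getV(const List& p, const std::string& nm) { return as<vec>(p[nm]); }

static double bce_loss(const rowvec& p, const vec& y) {
  const int n = p.n_elem;
  double L = 0.0;
  for (int j = 0; j < n; ++j) {
    double pc = std::min(std::max(p(j), 1e-7), 1.0 - 1e-7);
    L += -(y(j) * std::log(pc) + (1.0 - y(j)) * std::log(1.0 - pc));
  }
  return L / n;
}

// ------------------------------------------------------------- entry points

// Training-mode forward + backward. dropMask is (fcHidden x n) of
// 0 / (1-p)^-1 multipliers (all ones disables dropout).
// [[Rcpp::export]]
List nn_fwbw(arma::cube X, arma::vec y, List params, List cfgList,
             arma::mat dropMask) {
  NetConfig cfg = parseConfig(cfgList);
  const int n = X.n_slices;

  std::vector<cube> convIn, convPre, reluOut, bnXhat, poolIn;
  std::vector<Cube<uword>> poolIdx;
  std::vector<vec> bnMu, bnVar;

  cube cur = X;
  for (int l = 0; l < cfg.nConv; ++l) {
    const std::string tag = std::to_string(l + 1);
    convIn.push_back(cur);
    cube Z = conv_forward(cur, getM(params, "conv" + tag + "_W"),
                          getV(params, "conv" + tag + "_b"), cfg.k);
    convPre.push_back(Z);
    cube R = relu_c(Z);
    reluOut.push_back(R);
    cube B;
    if (cfg.batchNorm) {
      vec mu, varb; cube xh;
      B = bn_forward_train(R, getV(params, "bn" + tag + "_gamma"),
                           getV(params, "bn" + tag + "_beta"), mu, varb, xh);
      bnMu.push_back(mu); bnVar.push_back(varb); bnXhat.push_back(xh);
    } else B = R;
    poolIn.push_back(B);
    Cube<uword> idx;
    cur = pool_forward(B, cfg.pool, idx);
    poolIdx.push_back(idx);
  }

  // feature vector
  mat feat;
  LSTMCache ccF, ccB;
  Mat<uword> gmaxIdx, rnnMaxIdx;
  if (cfg.arch != 1) {
    lstm_forward(cur, getM(params, "lstm_fw_W"),
                 getM(params, "lstm_fw_U"),
                 getV(params, "lstm_fw_b"), false, ccF);
    lstm_forward(cur, getM(params, "lstm_bw_W"),
                 getM(params, "lstm_bw_U"),
                 getV(params, "lstm_bw_b"), true, ccB);
    const int Lr = cur.n_rows, H = cfg.H;
    if (cfg.rnnHead == 1) {
      // max over time of each hidden unit, both directions
      feat.set_size(2 * H, n);
      rnnMaxIdx.set_size(2 * H, n);
      for (int r = 0; r < H; ++r)
        for (int j = 0; j < n; ++j) {
          uword bs = 0; double bv = ccF.Hs(r, j, 0);
          for (int t = 1; t < Lr; ++t)
            if (ccF.Hs(r, j, t) > bv) { bv = ccF.Hs(r, j, t); bs = t; }
          feat(r, j) = bv; rnnMaxIdx(r, j) = bs;
          bs = 0; bv = ccB.Hs(r, j, 0);
          for (int t = 1; t < Lr; ++t)
            if (ccB.Hs(r, j, t) > bv) { bv = ccB.Hs(r, j, t); bs = t; }
          feat(H + r, j) = bv; rnnMaxIdx(H + r, j) = bs;
        }
    } else {
      // flatten the full bi-LSTM output: block t = [h_fw(t); h_bw(t)]
      feat.set_size(2 * H * Lr, n);
      for (int t = 0; t < Lr; ++t) {
        feat.rows(2 * H * t, 2 * H * t + H - 1) = ccF.Hs.slice(t);
        feat.rows(2 * H * t + H, 2 * H * t + 2 * H - 1) =
          ccB.Hs.slice(Lr - 1 - t);
      }
    }
  } else {
    const int C = cur.n_cols, L = cur.n_rows;
    feat.set_size(C, n);
    gmaxIdx.set_size(C, n);
    for (int s = 0; s < n; ++s)
      for (int c = 0; c < C; ++c) {
        uword best = 0; double bv = cur(0, c, s);
        for (int t = 1; t < L; ++t)
          if (cur(t, c, s) > bv) { bv = cur(t, c, s); best = t; }
        feat(c, s) = bv; gmaxIdx(c, s) = best;
      }
  }

  mat W1 = getM(params, "fc1_W"), W2 = getM(params, "fc2_W");
  vec b1 = getV(params, "fc1_b"), b2 = getV(params, "fc2_b");
  mat A1 = W1 * feat; A1.each_col() += b1;
  mat R1 = relu_m(A1);
  mat D = R1 % dropMask;
  mat Z2 = W2 * D; Z2.each_col() += b2;
  rowvec p = sigm(Z2).row(0);
  double loss = bce_loss(p, y);

  // ------------------------------------------------------------- backward
  List grads;
  rowvec dz = (p - y.t()) / (double)n;
  grads["fc2_W"] = mat(dz * D.t());
  grads["fc2_b"] = vec{accu(dz)};
  mat dD = W2.t() * dz;
  mat dR1 = dD % dropMask;
  mat dA1 = dR1 % conv_to<mat>::from(A1 > 0.0);
  grads["fc1_W"] = mat(dA1 * feat.t());
  grads["fc1_b"] = vec(sum(dA1, 1));
  mat dfeat = W1.t() * dA1;

  cube dcur(size(cur), fill::zeros);
  if (cfg.arch != 1) {
    const int H = cfg.H, Lr = cur.n_rows;
    cube dHf(H, n, Lr), dHb(H, n, Lr);
    if (cfg.rnnHead == 1) {
      dHf.zeros(); dHb.zeros();
      for (int r = 0; r < H; ++r)
        for (int j = 0; j < n; ++j) {
          dHf(r, j, rnnMaxIdx(r, j)) += dfeat(r, j);
          dHb(r, j, rnnMaxIdx(H + r, j)) += dfeat(H + r, j);
        }
    } else {
      for (int t = 0; t < Lr; ++t) {
        dHf.slice(t) = dfeat.rows(2 * H * t, 2 * H * t + H - 1);
        dHb.slice(Lr - 1 - t) =
          dfeat.rows(2 * H * t + H, 2 * H * t + 2 * H - 1);
      }
    }
    mat dWf, dUf, dWb, dUb; vec dbf, dbb;
    lstm_backward(cur, getM(params, "lstm_fw_W"), getM(params, "lstm_fw_U"),
                  false, ccF, dHf, dWf, dUf, dbf, dcur);
    lstm_backward(cur, getM(params, "lstm_bw_W"), getM(params, "lstm_bw_U"),
                  true, ccB, dHb, dWb, dUb, dbb, dcur);
    grads["lstm_fw_W"] = dWf; grads["lstm_fw_U"] = dUf; grads["lstm_fw_b"] = dbf;
    grads["lstm_bw_W"] = dWb; grads["lstm_bw_U"] = dUb; grads["lstm_bw_b"] = dbb;
  } else {
    const int C = cur.n_cols;
    for (int s = 0; s < n; ++s)
      for (int c = 0; c < C; ++c)
        dcur(gmaxIdx(c, s), c, s) += dfeat(c, s);
  }

  List bnBatch;
  for (int l = cfg.nConv - 1; l >= 0; --l) {
    const std::string tag = std::to_string(l + 1);
    cube dB = pool_backward(dcur, poolIdx[l], poolIn[l].n_rows);
    cube dR;
    if (cfg.batchNorm) {
      vec dgamma, dbeta;
      dR = bn_backward(dB, bnXhat[l], getV(params, "bn" + tag + "_gamma"),
                       bnVar[l], dgamma, dbeta);
      grads["bn" + tag + "_gamma"] = dgamma;
      grads["bn" + tag + "_beta"] = dbeta;
      const double m = (double)poolIn[l].n_rows * n;
      bnBatch["bn" + tag + "_mean"] = bnMu[l];
      bnBatch["bn" + tag + "_var"] = vec(bnVar[l] * (m / std::max(m - 1.0, 1.0)));
    } else dR = dB;
    cube dZ = dR % conv_to<cube>::from(convPre[l] > 0.0);
    mat dW; vec db;
    dcur = conv_backward(convIn[l], getM(params, "conv" + tag + "_W"),
                         dZ, cfg.k, dW, db);
    grads["conv" + tag + "_W"] = dW;
    grads["conv" + tag + "_b"] = db;
  }

  return List::create(_["loss"] = loss,
                      _["probs"] = NumericVector(p.begin(), p.end()),
                      _["grads"] = grads,
                      _["bnBatch"] = bnBatch);
}

// Deterministic eval-mode forward (running BN statistics, no dropout).
// [[Rcpp::export]]
NumericVector nn_predict_cpp(arma::cube X, List params, List bnState,
                             List cfgList) {
  NetConfig cfg = parseConfig(cfgList);
  cube cur = X;
  for (int l = 0; l < cfg.nConv; ++l) {
    const std::string tag = std::to_string(l + 1);
    cube Z = conv_forward(cur, getM(params, "conv" + tag + "_W"),
                          getV(params, "conv" + tag + "_b"), cfg.k);
    cube R = relu_c(Z);
    cube B;
    if (cfg.batchNorm)
      B = bn_forward_eval(R, getV(params, "bn" + tag + "_gamma"),
                          getV(params, "bn" + tag + "_beta"),
                          getV(bnState, "bn" + tag + "_mean"),
                          getV(bnState, "bn" + tag + "_var"));
    else B = R;
    Cube<uword> idx;
    cur = pool_forward(B, cfg.pool, idx);
  }
  mat feat;
  const int n = X.n_slices;
  if (cfg.arch != 1) {
    LSTMCache ccF, ccB;
    lstm_forward(cur, getM(params, "lstm_fw_W"),
                 getM(params, "lstm_fw_U"),
                 getV(params, "lstm_fw_b"), false, ccF);
    lstm_forward(cur, getM(params, "lstm_bw_W"),
                 getM(params, "lstm_bw_U"),
                 getV(params, "lstm_bw_b"), true, ccB);
    const int Lr = cur.n_rows, H = cfg.H;
    if (cfg.rnnHead == 1) {
      feat.set_size(2 * H, n);
      for (int r = 0; r < H; ++r)
        for (int j = 0; j < n; ++j) {
          double bf = ccF.Hs(r, j, 0), bb = ccB.Hs(r, j, 0);
          for (int t = 1; t < Lr; ++t) {
            bf = std::max(bf, ccF.Hs(r, j, t));
            bb = std::max(bb, ccB.Hs(r, j, t));
          }
          feat(r, j) = bf; feat(H + r, j) = bb;
        }
    } else {
      feat.set_size(2 * H * Lr, n);
      for (int t = 0; t < Lr; ++t) {
        feat.rows(2 * H * t, 2 * H * t + H - 1) = ccF.Hs.slice(t);
        feat.rows(2 * H * t + H, 2 * H * t + 2 * H - 1) =
          ccB.Hs.slice(Lr - 1 - t);
      }
    }
  } else {
    const int C = cur.n_cols, L = cur.n_rows;
    feat.set_size(C, n);
    for (int s = 0; s < n; ++s)
      for (int c = 0; c < C; ++c) {
        double bv = cur(0, c, s);
        for (int t = 1; t < L; ++t) bv = std::max(bv, cur(t, c, s));
        feat(c, s) = bv;
      }
  }
  mat A1 = getM(params, "fc1_W") * feat; A1.each_col() += getV(params, "fc1_b");
  mat R1 = relu_m(A1);
  mat Z2 = getM(params, "fc2_W") * R1; Z2.each_col() += getV(params, "fc2_b");
  rowvec p = sigm(Z2).row(0);
  return NumericVector(p.begin(), p.end());
}

// Hidden states of a single LSTM direction for one record, in original time
// order; used to cross-check the cell against the pure-R step oracle.
// [[Rcpp::export]]
arma::mat lstm_seq_cpp(arma::mat Xseq, arma::mat W, arma::mat U, arma::vec b,
                       bool reverse) {
  cube X(Xseq.n_rows, Xseq.n_cols, 1);
  X.slice(0) = Xseq;
  LSTMCache cc;
  lstm_forward(X, W, U, b, reverse, cc);
  const int L = Xseq.n_rows, H = U.n_rows / 4;
  mat Hout(L, H);
  for (int s = 0; s < L; ++s) {
    const int t = reverse ? (L - 1 - s) : s;
    Hout.row(t) = cc.Hs.slice(s).col(0).t();
  }
  return Hout;
}
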