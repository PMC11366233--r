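// Bi-directional LSTM sequence-to-sequence regressor: forward pass and
// full backpropagation through time, called from R. Batched over
// sequences: the input cube X has dimensions (batch, channels, time) so
// X.slice(t) is the batch x channels matrix at one timestep.
//
// The input projection X * W' (all timesteps) and the weight-gradient
// contractions dA' * X and dA' * H_prev are hoisted out of the time loop
// as single large GEMMs; only the hidden-state recurrence remains
// sequential.
//
// Parameter list layout (names fixed by the R side):
//   Wf, Uf, bf  forward-direction LSTM (4H x C, 4H x H, 4H)
//   Wb, Ub, bb  backward-direction LSTM
//   W1, b1      linear 1: 2H -> L2
//   W2, b2      linear 2: L2 -> L3
//   W3, b3      linear 3: L3 -> 1
// Gate column order inside the 4H blocks: input, forget, cell, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat activate(const mat& z, int act) {
  switch (act) {
    case 0: return clamp(z, 0.0, datum::inf);            // relu
    case 1: return z % ((z > 0) + 0.01 * (z <= 0));      // leaky_relu
    case 2: return tanh(z);
    case 3: return 1.0 / (1.0 + exp(-z));                // sigmoid
    default: Rcpp::stop("unknown activation code");
  }
}

// derivative expressed via pre-activation z and activation a
static mat activate_deriv(const mat& z, const mat& a, int act) {
  switch (act) {
    case 0: return conv_to<mat>::from(z > 0);
    case 1: return conv_to<mat>::from(z > 0) + 0.01 * (z <= 0);
    case 2: return 1.0 - square(a);
    case 3: return a % (1.0 - a);
    default: Rcpp::stop("unknown activation code");
  }
}

// flatten (B, C, T) to (B*T, C) with row index t*B + b
static mat flatten_bt(const cube& X) {
  const uword B = X.n_rows, C = X.n_cols, T = X.n_slices;
  mat out(B * T, C);
  for (uword t = 0; t < T; ++t) out.rows(t * B, t * B + B - 1) = X.slice(t);
  return out;
}

struct LstmCache {
  cube G;        // gates after nonlinearity (B, 4H, T): [i f g o]
  cube C, TC, H; // cell state, tanh(cell), hidden state (B, H, T)
};

// One LSTM direction over the whole batch. dir = +1 runs t = 0..T-1,
// dir = -1 runs t = T-1..0 (the reverse pass); states are stored at their
// true time index either way. Xf is the flattened (B*T, C) input.
static void lstm_forward(const mat& Xf, uword B, uword T, const mat& W,
                         const mat& U, const vec& b, int dir,
                         LstmCache& cc) {
  const uword H = U.n_cols;
  cc.G.set_size(B, 4 * H, T);
  cc.C.set_size(B, H, T); cc.TC.set_size(B, H, T); cc.H.set_size(B, H, T);
  mat XW = Xf * W.t();               // one big GEMM for every timestep
  XW.each_row() += b.t();
  mat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  mat A(B, 4 * H);
  const mat Ut = U.t();
  const uword BH = B * H;
  for (uword s = 0; s < T; ++s) {
    const uword t = (dir > 0) ? s : (T - 1 - s);
    A = XW.rows(t * B, t * B + B - 1);
    A += h_prev * Ut;
    // fused gate nonlinearities + state update, one pass over memory
    mat& Gt = cc.G.slice(t);
    double* gp = Gt.memptr();
    const double* ap = A.memptr();
    double* cp = cc.C.slice(t).memptr();
    double* tcp = cc.TC.slice(t).memptr();
    double* hp = cc.H.slice(t).memptr();
    const double* cprev = c_prev.memptr();
    for (uword k = 0; k < BH; ++k) {
      const double i = 1.0 / (1.0 + std::exp(-ap[k]));
      const double f = 1.0 / (1.0 + std::exp(-ap[BH + k]));
      const double g = std::tanh(ap[2 * BH + k]);
      const double o = 1.0 / (1.0 + std::exp(-ap[3 * BH + k]));
      const double c = f * cprev[k] + i * g;
      const double tc = std::tanh(c);
      gp[k] = i; gp[BH + k] = f; gp[2 * BH + k] = g; gp[3 * BH + k] = o;
      cp[k] = c; tcp[k] = tc; hp[k] = o * tc;
    }
    h_prev = cc.H.slice(t);
    c_prev = cc.C.slice(t);
  }
}

// BPTT for one direction. dH holds dLoss/dh at every time index.
static void lstm_backward(const mat& Xf, uword B, uword T, const mat& U,
                          const LstmCache& cc, const cube& dH, int dir,
                          mat& dW, mat& dU, vec& db) {
  const uword H = U.n_cols;
  cube dA(B, 4 * H, T);
  mat dh_carry(B, H, fill::zeros), dc_carry(B, H, fill::zeros);
  const uword BH = B * H;
  for (uword s = 0; s < T; ++s) {
    // reverse of the forward processing order
    const uword t = (dir > 0) ? (T - 1 - s) : s;
    const bool first_step = (dir > 0) ? (t == 0) : (t == T - 1);
    const uword tp = first_step ? t : ((dir > 0) ? (t - 1) : (t + 1));
    const double* gp = cc.G.slice(t).memptr();
    const double* tcp = cc.TC.slice(t).memptr();
    const double* cprev = cc.C.slice(tp).memptr();   // unused if first
    const double* dhp = dH.slice(t).memptr();
    double* dcc = dc_carry.memptr();
    double* dhc = dh_carry.memptr();
    mat& dAt = dA.slice(t);
    double* dap = dAt.memptr();
    for (uword k = 0; k < BH; ++k) {
      const double i = gp[k], f = gp[BH + k], g = gp[2 * BH + k],
                   o = gp[3 * BH + k], tc = tcp[k];
      const double dh = dhp[k] + dhc[k];
      const double dc = dh * o * (1.0 - tc * tc) + dcc[k];
      dap[k] = dc * g * i * (1.0 - i);
      dap[BH + k] = first_step ? 0.0 : dc * cprev[k] * f * (1.0 - f);
      dap[2 * BH + k] = dc * i * (1.0 - g * g);
      dap[3 * BH + k] = dh * tc * o * (1.0 - o);
      dcc[k] = dc * f;
    }
    dh_carry = dAt * U;
  }
  // contract the per-step gradients in two large GEMMs
  mat dAf = flatten_bt(dA);
  dW = dAf.t() * Xf;
  db = sum(dAf, 0).t();
  // H_prev flattened: hidden state one recurrence step earlier
  mat Hprev(B * T, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const bool first_step = (dir > 0) ? (t == 0) : (t == T - 1);
    if (!first_step) {
      const uword tp = (dir > 0) ? (t - 1) : (t + 1);
      Hprev.rows(t * B, t * B + B - 1) = cc.H.slice(tp);
    }
  }
  dU = dAf.t() * Hprev;
}

struct HeadCache {
  mat Hcat, Z1, A1, D1, Z2, A2, D2;
};

// concatenated hidden states through the three linear layers; mask1/mask2
// are inverted-dropout masks (all ones at inference)
static mat head_forward(const LstmCache& fw, const LstmCache& bw,
                        const Rcpp::List& params, int act,
                        const mat& mask1, const mat& mask2, HeadCache& hc) {
  const uword B = fw.H.n_rows, H = fw.H.n_cols, T = fw.H.n_slices;
  const mat W1 = params["W1"]; const vec b1 = params["b1"];
  const mat W2 = params["W2"]; const vec b2 = params["b2"];
  const mat W3 = params["W3"]; const vec b3 = params["b3"];
  hc.Hcat.set_size(B * T, 2 * H);
  for (uword t = 0; t < T; ++t) {
    hc.Hcat.submat(t * B, 0, t * B + B - 1, H - 1) = fw.H.slice(t);
    hc.Hcat.submat(t * B, H, t * B + B - 1, 2 * H - 1) = bw.H.slice(t);
  }
  hc.Z1 = hc.Hcat * W1.t();
  hc.Z1.each_row() += b1.t();
  hc.A1 = activate(hc.Z1, act);
  hc.D1 = hc.A1 % mask1;
  hc.Z2 = hc.D1 * W2.t();
  hc.Z2.each_row() += b2.t();
  hc.A2 = activate(hc.Z2, act);
  hc.D2 = hc.A2 % mask2;
  mat Y = hc.D2 * W3.t();
  Y.each_row() += b3.t();
  return Y;   // (B*T) x 1
}

static mat reshape_pred(const mat& Y, uword B, uword T) {
  mat y(B, T);
  for (uword t = 0; t < T; ++t) y.col(t) = Y.rows(t * B, t * B + B - 1);
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_bilstm_predict(const arma::cube& X, const Rcpp::List& params,
                             int act) {
  const uword B = X.n_rows, T = X.n_slices;
  const mat Wf = params["Wf"], Uf = params["Uf"];
  const mat Wb = params["Wb"], Ub = params["Ub"];
  const vec bf = params["bf"], bb = params["bb"];
  mat Xf = flatten_bt(X);
  LstmCache fw, bw;
  lstm_forward(Xf, B, T, Wf, Uf, bf, +1, fw);
  lstm_forward(Xf, B, T, Wb, Ub, bb, -1, bw);
  HeadCache hc;
  const uword L2 = Rcpp::as<mat>(params["W1"]).n_rows;
  const uword L3 = Rcpp::as<mat>(params["W2"]).n_rows;
  mat ones1(B * T, L2, fill::ones), ones2(B * T, L3, fill::ones);
  mat Y = head_forward(fw, bw, params, act, ones1, ones2, hc);
  return reshape_pred(Y, B, T);
}

// Forward + backward for one training batch under the batch-RMSE loss
// L = sqrt(mean((pred - target)^2)). in_mask is the inverted-dropout mask
// applied to the input cube; mask1/mask2 apply after the first two linear
// activations.
// [[Rcpp::export]]
Rcpp::List cpp_bilstm_grad(const arma::cube& X, const arma::mat& target,
                           const Rcpp::List& params, int act,
                           const arma::cube& in_mask,
                           const arma::mat& mask1, const arma::mat& mask2) {
  const uword B = X.n_rows, T = X.n_slices;
  if (target.n_rows != B || target.n_cols != T)
    Rcpp::stop("target dimensions do not match the input batch");
  mat Xf = flatten_bt(X) % flatten_bt(in_mask);
  const mat Wf = params["Wf"], Uf = params["Uf"];
  const mat Wb = params["Wb"], Ub = params["Ub"];
  const vec bf = params["bf"], bb = params["bb"];
  const mat W1 = params["W1"], W2 = params["W2"], W3 = params["W3"];

  LstmCache fw, bw;
  lstm_forward(Xf, B, T, Wf, Uf, bf, +1, fw);
  lstm_forward(Xf, B, T, Wb, Ub, bb, -1, bw);
  HeadCache hc;
  mat Y = head_forward(fw, bw, params, act, mask1, mask2, hc);
  mat pred = reshape_pred(Y, B, T);

  const double n = static_cast<double>(B) * static_cast<double>(T);
  mat resid = pred - target;
  double loss = std::sqrt(accu(square(resid)) / n);

  // d loss / d pred, flattened to match Y's (B*T) x 1 layout
  mat dY(B * T, 1, fill::zeros);
  if (loss > 0) {
    for (uword t = 0; t < T; ++t)
      dY.rows(t * B, t * B + B - 1) = resid.col(t) / (n * loss);
  }

  // head backward
  mat dW3 = dY.t() * hc.D2;
  vec db3 = sum(dY, 0).t();
  mat dD2 = dY * W3;
  mat dZ2 = (dD2 % mask2) % activate_deriv(hc.Z2, hc.A2, act);
  mat dW2 = dZ2.t() * hc.D1;
  vec db2 = sum(dZ2, 0).t();
  mat dD1 = dZ2 * W2;
  mat dZ1 = (dD1 % mask1) % activate_deriv(hc.Z1, hc.A1, act);
  mat dW1 = dZ1.t() * hc.Hcat;
  vec db1 = sum(dZ1, 0).t();
  mat dHcat = dZ1 * W1;   // (B*T) x 2H

  const uword H = Uf.n_cols;
  cube dHf(B, H, T), dHb(B, H, T);
  for (uword t = 0; t < T; ++t) {
    dHf.slice(t) = dHcat.submat(t * B, 0, t * B + B - 1, H - 1);
    dHb.slice(t) = dHcat.submat(t * B, H, t * B + B - 1, 2 * H - 1);
  }

  mat dWf, dUf, dWb, dUb;
  vec dbf, dbb;
  lstm_backward(Xf, B, T, Uf, fw, dHf, +1, dWf, dUf, dbf);
  lstm_backward(Xf, B, T, Ub, bw, dHb, -1, dWb, dUb, dbb);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("pred") = pred,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("Wf") = dWf, Rcpp::Named("Uf") = dUf,
      Rcpp::Named("bf") = dbf,
      Rcpp::Named("Wb") = dWb, Rcpp::Named("Ub") = dUb,
      Rcpp::Named("bb") = dbb,
      Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
      Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2,
      Rcpp::Named("W3") = dW3, Rcpp::Named("b3") = db3));
}
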