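// Hand-rolled BPTT for the BiLSTM-I encoder-decoder imputer and the
// BRITS-I-style recurrent baseline. All tensors are batched: a cube has
// dimensions (batch, features, time); slice t is a batch x feature matrix.
//
// Parameter orientation: a linear map with input dim p and output dim r is a
// p x r matrix applied as X * W (rows = batch), plus a length-r bias row.
// LSTM gate blocks are stored column-wise in the order [i | f | g | o].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmTrace {           // stored activations for one direction
  std::vector<mat> Xtil, Xc, I, F, G, O, C, TC, H, Hprev, Cprev;
};

// forward pass of one LSTM layer step; returns H, C and stores gates
static void lstm_step(const mat& In, const mat& Hp, const mat& Cp,
                      const mat& W, const rowvec& b, const uword h,
                      mat& I, mat& F, mat& G, mat& O, mat& C, mat& TC,
                      mat& H) {
  mat Zin = join_rows(In, Hp);
  mat Gts = Zin * W;
  Gts.each_row() += b;
  I = sigm(Gts.cols(0, h - 1));
  F = sigm(Gts.cols(h, 2 * h - 1));
  G = tanh(Gts.cols(2 * h, 3 * h - 1));
  O = sigm(Gts.cols(3 * h, 4 * h - 1));
  C = F % Cp + I % G;
  TC = tanh(C);
  H = O % TC;
}

// backward through one LSTM step. dH: gradient wrt H_t (all paths),
// dC io: carried cell gradient (in: from t+1; out: wrt C_{t-1}).
// Returns gradient wrt the step input (dIn) and wrt H_{t-1} via the
// recurrence (dHp). Accumulates dW, db.
static void lstm_step_back(const mat& In, const mat& Hp, const mat& Cp,
                           const mat& W, const uword h, const mat& I,
                           const mat& F, const mat& G, const mat& O,
                           const mat& TC, const mat& dH, mat& dC, mat& dW,
                           rowvec& db, mat& dIn, mat& dHp) {
  mat dO = dH % TC;
  dC += dH % O % (1.0 - TC % TC);
  mat dI = dC % G;
  mat dF = dC % Cp;
  mat dG = dC % I;
  mat dCp = dC % F;
  mat dGts = join_rows(join_rows(dI % I % (1.0 - I), dF % F % (1.0 - F)),
                       join_rows(dG % (1.0 - G % G), dO % O % (1.0 - O)));
  mat Zin = join_rows(In, Hp);
  dW += Zin.t() * dGts;
  db += sum(dGts, 0);
  mat dZin = dGts * W.t();
  const uword p = In.n_cols;
  dIn = dZin.cols(0, p - 1);
  dHp = dZin.cols(p, p + h - 1);
  dC = dCp;
}

// Encoder direction forward. ord gives the processing order of time slices
// (0..w-1 for the forward reader, reversed for the backward reader).
static double encoder_forward(const cube& x, const cube& m, const cube& tr,
                              const cube& lm, const uvec& ord, const mat& Wx,
                              const rowvec& bx, const mat& W, const rowvec& b,
                              const uword h, LstmTrace& tc,
                              std::vector<mat>& Hout) {
  const uword w = x.n_slices, B = x.n_rows;
  const uword nf = x.n_cols;
  mat Hp(B, h, fill::zeros), Cp(B, h, fill::zeros);
  double loss = 0.0;
  tc.Xtil.resize(w); tc.Xc.resize(w); tc.I.resize(w); tc.F.resize(w);
  tc.G.resize(w); tc.O.resize(w); tc.C.resize(w); tc.TC.resize(w);
  tc.H.resize(w); tc.Hprev.resize(w); tc.Cprev.resize(w);
  (void)nf;
  for (uword idx = 0; idx < w; ++idx) {
    const uword t = ord(idx);
    mat Xt = x.slice(t), Mt = m.slice(t);
    mat Xtil = Hp * Wx;
    Xtil.each_row() += bx;
    mat Xc = Mt % Xt + (1.0 - Mt) % Xtil;
    mat I, F, G, O, C, TC, H;
    lstm_step(Xc, Hp, Cp, W, b, h, I, F, G, O, C, TC, H);
    loss += accu(lm.slice(t) % abs(tr.slice(t) - Xtil));
    tc.Xtil[t] = Xtil; tc.Xc[t] = Xc; tc.I[t] = I; tc.F[t] = F;
    tc.G[t] = G; tc.O[t] = O; tc.C[t] = C; tc.TC[t] = TC; tc.H[t] = H;
    tc.Hprev[t] = Hp; tc.Cprev[t] = Cp;
    Hout[t] = H;
    Hp = H; Cp = C;
  }
  return loss;
}

// Encoder direction backward. dHenc[t]: gradient flowing into H_t from the
// decoder. Accumulates parameter gradients; loss term gradient uses 1/N.
static void encoder_backward(const cube& x, const cube& m, const cube& tr,
                             const cube& lm, const uvec& ord, const mat& Wx,
                             const mat& W, const uword h, const double invN,
                             const LstmTrace& tc, const std::vector<mat>& dHenc,
                             mat& dWx, rowvec& dbx, mat& dW, rowvec& db) {
  const uword w = x.n_slices, B = x.n_rows;
  mat dHc(B, h, fill::zeros), dC(B, h, fill::zeros);
  for (int idx = (int)w - 1; idx >= 0; --idx) {
    const uword t = ord(idx);
    mat dH = dHenc[t] + dHc;
    mat dXc, dHp;
    lstm_step_back(tc.Xc[t], tc.Hprev[t], tc.Cprev[t], W, h, tc.I[t], tc.F[t],
                   tc.G[t], tc.O[t], tc.TC[t], dH, dC, dW, db, dXc, dHp);
    mat dXtil = dXc % (1.0 - m.slice(t)) +
                invN * (lm.slice(t) % sign(tc.Xtil[t] - tr.slice(t)));
    dWx += tc.Hprev[t].t() * dXtil;
    dbx += sum(dXtil, 0);
    dHc = dHp + dXtil * Wx.t();
  }
}

// Full BiLSTM-I pass. x: inputs with missing entries zeroed; m: observation
// mask; tr: training target (zeros at inference); lm: loss mask. Returns the
// three loss components (each averaged over scored positions), the decoder
// output, the per-direction estimates, and (optionally) parameter gradients.
// [[Rcpp::export]]
Rcpp::List cpp_bilstm_pass(const arma::cube& x, const arma::cube& m,
                           const arma::cube& tr, const arma::cube& lm,
                           const Rcpp::List& params, const bool want_grad) {
  const uword w = x.n_slices, B = x.n_rows, nf = x.n_cols;

  const mat Wx_f = params["Wx_f"]; const rowvec bx_f = params["bx_f"];
  const mat W_f = params["W_f"];   const rowvec b_f = params["b_f"];
  const mat Wx_b = params["Wx_b"]; const rowvec bx_b = params["bx_b"];
  const mat W_b = params["W_b"];   const rowvec b_b = params["b_b"];
  const mat W_d = params["W_d"];   const rowvec b_d = params["b_d"];
  const mat Wy = params["Wy"];     const rowvec by = params["by"];
  const uword h = W_f.n_cols / 4, hd = W_d.n_cols / 4;

  double N = accu(lm);
  const double invN = N > 0 ? 1.0 / N : 0.0;

  uvec ord_f = regspace<uvec>(0, w - 1);
  uvec ord_b = reverse(ord_f);

  LstmTrace tf, tb;
  std::vector<mat> Hf(w), Hb(w);
  double l_f = encoder_forward(x, m, tr, lm, ord_f, Wx_f, bx_f, W_f, b_f, h,
                               tf, Hf);
  double l_b = encoder_forward(x, m, tr, lm, ord_b, Wx_b, bx_b, W_b, b_b, h,
                               tb, Hb);

  // decoder
  LstmTrace td;
  td.Xc.resize(w); td.I.resize(w); td.F.resize(w); td.G.resize(w);
  td.O.resize(w); td.C.resize(w); td.TC.resize(w); td.H.resize(w);
  td.Hprev.resize(w); td.Cprev.resize(w);
  cube Y(B, nf, w), Xtil_f(B, nf, w), Xtil_b(B, nf, w);
  {
    mat Sp(B, hd, fill::zeros), Cp(B, hd, fill::zeros);
    for (uword t = 0; t < w; ++t) {
      mat In = join_rows(Hf[t], Hb[t]);
      mat I, F, G, O, C, TC, S;
      lstm_step(In, Sp, Cp, W_d, b_d, hd, I, F, G, O, C, TC, S);
      mat Yt = S * Wy;
      Yt.each_row() += by;
      Y.slice(t) = Yt;
      td.Xc[t] = In; td.I[t] = I; td.F[t] = F; td.G[t] = G; td.O[t] = O;
      td.C[t] = C; td.TC[t] = TC; td.H[t] = S; td.Hprev[t] = Sp;
      td.Cprev[t] = Cp;
      Sp = S; Cp = C;
      Xtil_f.slice(t) = tf.Xtil[t];
      Xtil_b.slice(t) = tb.Xtil[t];
    }
  }

  double l_y = 0.0;
  for (uword t = 0; t < w; ++t)
    l_y += accu(lm.slice(t) % abs(tr.slice(t) - Y.slice(t)));
  l_f *= invN; l_b *= invN; l_y *= invN;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("l_f") = l_f, Rcpp::Named("l_b") = l_b,
      Rcpp::Named("l_y") = l_y, Rcpp::Named("total") = l_f + l_b + l_y,
      Rcpp::Named("y") = Y, Rcpp::Named("xtil_f") = Xtil_f,
      Rcpp::Named("xtil_b") = Xtil_b, Rcpp::Named("n_scored") = N);
  if (!want_grad) return out;

  // ---- backward ----
  mat dWx_f(size(Wx_f), fill::zeros), dW_f(size(W_f), fill::zeros);
  rowvec dbx_f(size(bx_f), fill::zeros), db_f(size(b_f), fill::zeros);
  mat dWx_b(size(Wx_b), fill::zeros), dW_b(size(W_b), fill::zeros);
  rowvec dbx_b(size(bx_b), fill::zeros), db_b(size(b_b), fill::zeros);
  mat dW_d(size(W_d), fill::zeros), dWy(size(Wy), fill::zeros);
  rowvec db_d(size(b_d), fill::zeros), dby(size(by), fill::zeros);

  std::vector<mat> dHf(w), dHb(w);
  {
    mat dSc(B, hd, fill::zeros), dC(B, hd, fill::zeros);
    for (int t = (int)w - 1; t >= 0; --t) {
      mat dY = invN * (lm.slice(t) % sign(Y.slice(t) - tr.slice(t)));
      dWy += td.H[t].t() * dY;
      dby += sum(dY, 0);
      mat dS = dY * Wy.t() + dSc;
      mat dIn, dSp;
      lstm_step_back(td.Xc[t], td.Hprev[t], td.Cprev[t], W_d, hd, td.I[t],
                     td.F[t], td.G[t], td.O[t], td.TC[t], dS, dC, dW_d, db_d,
                     dIn, dSp);
      dHf[t] = dIn.cols(0, h - 1);
      dHb[t] = dIn.cols(h, 2 * h - 1);
      dSc = dSp;
    }
  }
  encoder_backward(x, m, tr, lm, ord_f, Wx_f, W_f, h, invN, tf, dHf, dWx_f,
                   dbx_f, dW_f, db_f);
  encoder_backward(x, m, tr, lm, ord_b, Wx_b, W_b, h, invN, tb, dHb, dWx_b,
                   dbx_b, dW_b, db_b);

  out["grads"] = Rcpp::List::create(
      Rcpp::Named("Wx_f") = dWx_f, Rcpp::Named("bx_f") = dbx_f,
      Rcpp::Named("W_f") = dW_f, Rcpp::Named("b_f") = db_f,
      Rcpp::Named("Wx_b") = dWx_b, Rcpp::Named("bx_b") = dbx_b,
      Rcpp::Named("W_b") = dW_b, Rcpp::Named("b_b") = db_b,
      Rcpp::Named("W_d") = dW_d, Rcpp::Named("b_d") = db_d,
      Rcpp::Named("Wy") = dWy, Rcpp::Named("by") = dby);
  return out;
}

// ---------------- BRITS-I (RITS-I run in both directions) ----------------

struct RitsTrace {
  std::vector<mat> Xtil, Xc, I, F, G, O, C, TC, H, Hdec, Hprev, Cprev, U, Gam;
};

static double rits_forward(const cube& x, const cube& m, const cube& tr,
                           const cube& lm, const cube& del, const uvec& ord,
                           const mat& Wg, const rowvec& bg, const mat& Wx,
                           const rowvec& bx, const mat& W, const rowvec& b,
                           const uword h, RitsTrace& tc) {
  const uword w = x.n_slices, B = x.n_rows;
  mat Hp(B, h, fill::zeros), Cp(B, h, fill::zeros);
  double loss = 0.0;
  tc.Xtil.resize(w); tc.Xc.resize(w); tc.I.resize(w); tc.F.resize(w);
  tc.G.resize(w); tc.O.resize(w); tc.C.resize(w); tc.TC.resize(w);
  tc.H.resize(w); tc.Hdec.resize(w); tc.Hprev.resize(w); tc.Cprev.resize(w);
  tc.U.resize(w); tc.Gam.resize(w);
  for (uword idx = 0; idx < w; ++idx) {
    const uword t = ord(idx);
    mat U = del.slice(t) * Wg;
    U.each_row() += bg;
    mat Gam = exp(-max(U, zeros(size(U))));   // temporal decay in (0, 1]
    mat Hdec = Gam % Hp;
    mat Xtil = Hdec * Wx;
    Xtil.each_row() += bx;
    mat Xc = m.slice(t) % x.slice(t) + (1.0 - m.slice(t)) % Xtil;
    mat I, F, G, O, C, TC, H;
    lstm_step(Xc, Hdec, Cp, W, b, h, I, F, G, O, C, TC, H);
    loss += accu(lm.slice(t) % abs(tr.slice(t) - Xtil));
    tc.Xtil[t] = Xtil; tc.Xc[t] = Xc; tc.I[t] = I; tc.F[t] = F; tc.G[t] = G;
    tc.O[t] = O; tc.C[t] = C; tc.TC[t] = TC; tc.H[t] = H; tc.Hdec[t] = Hdec;
    tc.Hprev[t] = Hp; tc.Cprev[t] = Cp; tc.U[t] = U; tc.Gam[t] = Gam;
    Hp = H; Cp = C;
  }
  return loss;
}

static void rits_backward(const cube& x, const cube& m, const cube& tr,
                          const cube& lm, const cube& del, const uvec& ord,
                          const mat& Wg, const mat& Wx, const mat& W,
                          const uword h, const double invN,
                          const std::vector<mat>& dXtil_extra,
                          const RitsTrace& tc, mat& dWg, rowvec& dbg, mat& dWx,
                          rowvec& dbx, mat& dW, rowvec& db) {
  const uword w = x.n_slices, B = x.n_rows;
  mat dHc(B, h, fill::zeros), dC(B, h, fill::zeros);
  for (int idx = (int)w - 1; idx >= 0; --idx) {
    const uword t = ord(idx);
    mat dXc, dHdec_l;
    lstm_step_back(tc.Xc[t], tc.Hdec[t], tc.Cprev[t], W, h, tc.I[t], tc.F[t],
                   tc.G[t], tc.O[t], tc.TC[t], dHc, dC, dW, db, dXc, dHdec_l);
    mat dXtil = dXc % (1.0 - m.slice(t)) +
                invN * (lm.slice(t) % sign(tc.Xtil[t] - tr.slice(t))) +
                dXtil_extra[t];
    dWx += tc.Hdec[t].t() * dXtil;
    dbx += sum(dXtil, 0);
    mat dHdec = dHdec_l + dXtil * Wx.t();
    mat dGam = dHdec % tc.Hprev[t];
    mat dHp = dHdec % tc.Gam[t];
    mat dU = -tc.Gam[t] % dGam % conv_to<mat>::from(tc.U[t] > 0);
    dWg += del.slice(t).t() * dU;
    dbg += sum(dU, 0);
    dHc = dHp;
  }
}

// Full BRITS-I pass: the decay-adjusted unidirectional imputer run forward
// and backward; the final estimate is the mean of the two directional
// estimates, and the loss adds a direction-consistency penalty.
// del_f / del_b: time since the last observation, per slot, looking
// backwards / forwards respectively.
// [[Rcpp::export]]
Rcpp::List cpp_brits_pass(const arma::cube& x, const arma::cube& m,
                          const arma::cube& tr, const arma::cube& lm,
                          const arma::cube& del_f, const arma::cube& del_b,
                          const Rcpp::List& params, const bool want_grad) {
  const uword w = x.n_slices, B = x.n_rows, nf = x.n_cols;

  const mat Wg_f = params["Wg_f"]; const rowvec bg_f = params["bg_f"];
  const mat Wx_f = params["Wx_f"]; const rowvec bx_f = params["bx_f"];
  const mat W_f = params["W_f"];   const rowvec b_f = params["b_f"];
  const mat Wg_b = params["Wg_b"]; const rowvec bg_b = params["bg_b"];
  const mat Wx_b = params["Wx_b"]; const rowvec bx_b = params["bx_b"];
  const mat W_b = params["W_b"];   const rowvec b_b = params["b_b"];
  const uword h = W_f.n_cols / 4;

  double N = accu(lm);
  const double invN = N > 0 ? 1.0 / N : 0.0;
  const double invM = 1.0 / (double)(w * B * nf);

  uvec ord_f = regspace<uvec>(0, w - 1);
  uvec ord_b = reverse(ord_f);

  RitsTrace tf, tb;
  double l_f = rits_forward(x, m, tr, lm, del_f, ord_f, Wg_f, bg_f, Wx_f,
                            bx_f, W_f, b_f, h, tf) * invN;
  double l_b = rits_forward(x, m, tr, lm, del_b, ord_b, Wg_b, bg_b, Wx_b,
                            bx_b, W_b, b_b, h, tb) * invN;

  cube Xf(B, nf, w), Xb(B, nf, w), Yc(B, nf, w);
  double l_cons = 0.0;
  for (uword t = 0; t < w; ++t) {
    Xf.slice(t) = tf.Xtil[t];
    Xb.slice(t) = tb.Xtil[t];
    Yc.slice(t) = 0.5 * (Xf.slice(t) + Xb.slice(t));
    l_cons += accu(abs(Xf.slice(t) - Xb.slice(t)));
  }
  l_cons *= invM;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("l_f") = l_f, Rcpp::Named("l_b") = l_b,
      Rcpp::Named("l_cons") = l_cons,
      Rcpp::Named("total") = l_f + l_b + l_cons, Rcpp::Named("y") = Yc,
      Rcpp::Named("xtil_f") = Xf, Rcpp::Named("xtil_b") = Xb,
      Rcpp::Named("n_scored") = N);
  if (!want_grad) return out;

  std::vector<mat> ex_f(w), ex_b(w);
  for (uword t = 0; t < w; ++t) {
    mat s = invM * sign(Xf.slice(t) - Xb.slice(t));
    ex_f[t] = s;
    ex_b[t] = -s;
  }

  mat dWg_f(size(Wg_f), fill::zeros), dWx_f(size(Wx_f), fill::zeros),
      dW_f(size(W_f), fill::zeros);
  rowvec dbg_f(size(bg_f), fill::zeros), dbx_f(size(bx_f), fill::zeros),
      db_f(size(b_f), fill::zeros);
  mat dWg_b(size(Wg_b), fill::zeros), dWx_b(size(Wx_b), fill::zeros),
      dW_b(size(W_b), fill::zeros);
  rowvec dbg_b(size(bg_b), fill::zeros), dbx_b(size(bx_b), fill::zeros),
      db_b(size(b_b), fill::zeros);

  rits_backward(x, m, tr, lm, del_f, ord_f, Wg_f, Wx_f, W_f, h, invN, ex_f,
                tf, dWg_f, dbg_f, dWx_f, dbx_f, dW_f, db_f);
  rits_backward(x, m, tr, lm, del_b, ord_b, Wg_b, Wx_b, W_b, h, invN, ex_b,
                tb, dWg_b, dbg_b, dWx_b, dbx_b, dW_b, db_b);

  out["grads"] = Rcpp::List::create(
      Rcpp::Named("Wg_f") = dWg_f, Rcpp::Named("bg_f") = dbg_f,
      Rcpp::Named("Wx_f") = dWx_f, Rcpp::Named("bx_f") = dbx_f,
      Rcpp::Named("W_f") = dW_f, Rcpp::Named("b_f") = db_f,
      Rcpp::Named("Wg_b") = dWg_b, Rcpp::Named("bg_b") = dbg_b,
      Rcpp::Named("Wx_b") = dWx_b, Rcpp::Named("bx_b") = dbx_b,
      Rcpp::Named("W_b") = dW_b, Rcpp::Named("b_b") = db_b);
  return out;
}
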