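// Shared-weight bidirectional GRU with additive attention and a
// position-wise softmax readout.  One GRU weight set processes both the
// forward-strand window and its reverse complement; the reverse stream's
// outputs are re-reversed to forward coordinates before averaging so
// position t of both streams refers to the same base.  Attention scores
// each averaged position output against the averaged final hidden state
// (additive / Bahdanau form); the context vector joins each position's
// features in the dense softmax layer.
//
// Array layout: batches are cubes of shape (B x F x T) — slice t is the
// B x F matrix at time t.  All math is double precision; gradients are
// exact (verified against numerical differentiation in the test suite).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruWeights {
  mat Wz, Wr, Wh;   // input -> gates (F x U)
  mat Uz, Ur, Uh;   // recurrent (U x U)
  rowvec bz, br, bh;
};

struct GruCache {
  cube Z, R, Htl, H;  // each B x U x T
};

static GruWeights unpack_gru(const List& p) {
  GruWeights w;
  w.Wz = Rcpp::as<mat>(p["Wz"]); w.Wr = Rcpp::as<mat>(p["Wr"]);
  w.Wh = Rcpp::as<mat>(p["Wh"]);
  w.Uz = Rcpp::as<mat>(p["Uz"]); w.Ur = Rcpp::as<mat>(p["Ur"]);
  w.Uh = Rcpp::as<mat>(p["Uh"]);
  w.bz = Rcpp::as<rowvec>(p["bz"]); w.br = Rcpp::as<rowvec>(p["br"]);
  w.bh = Rcpp::as<rowvec>(p["bh"]);
  return w;
}

static void gru_forward(const cube& X, const GruWeights& w, GruCache& c) {
  const uword B = X.n_rows, T = X.n_slices, U = w.Uz.n_rows;
  c.Z.set_size(B, U, T); c.R.set_size(B, U, T);
  c.Htl.set_size(B, U, T); c.H.set_size(B, U, T);
  mat h(B, U, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const mat& x = X.slice(t);
    mat Z = sigm(x * w.Wz + h * w.Uz + repmat(w.bz, B, 1));
    mat R = sigm(x * w.Wr + h * w.Ur + repmat(w.br, B, 1));
    mat Htl = tanh(x * w.Wh + (R % h) * w.Uh + repmat(w.bh, B, 1));
    mat hn = (1.0 - Z) % h + Z % Htl;
    c.Z.slice(t) = Z; c.R.slice(t) = R; c.Htl.slice(t) = Htl;
    c.H.slice(t) = hn;
    h = hn;
  }
}

struct GruGrads {
  mat Wz, Wr, Wh, Uz, Ur, Uh;
  rowvec bz, br, bh;
  void init(uword F, uword U) {
    Wz.zeros(F, U); Wr.zeros(F, U); Wh.zeros(F, U);
    Uz.zeros(U, U); Ur.zeros(U, U); Uh.zeros(U, U);
    bz.zeros(U); br.zeros(U); bh.zeros(U);
  }
};

// Backpropagation through time for one stream.  dH holds per-time
// gradients on the outputs h_t; dh_final is an extra gradient on the
// final hidden state (from the attention summary path).  Accumulates
// into g (weights are shared across streams, so both streams add here).
static void gru_backward(const cube& X, const GruWeights& w,
                         const GruCache& c, const cube& dH,
                         const mat& dh_final, GruGrads& g) {
  const uword B = X.n_rows, T = X.n_slices, U = w.Uz.n_rows;
  mat dh = dh_final;
  for (uword ti = T; ti-- > 0;) {
    dh += dH.slice(ti);
    const mat& Z = c.Z.slice(ti);
    const mat& R = c.R.slice(ti);
    const mat& Htl = c.Htl.slice(ti);
    mat hprev = (ti == 0) ? mat(B, U, fill::zeros) : c.H.slice(ti - 1);

    mat dZ = dh % (Htl - hprev);
    mat dHtl_pre = (dh % Z) % (1.0 - Htl % Htl);
    mat dhprev = dh % (1.0 - Z);

    mat dRh = dHtl_pre * w.Uh.t();   // grad wrt (R % hprev)
    mat dR_pre = (dRh % hprev) % R % (1.0 - R);
    dhprev += dRh % R;
    mat dZ_pre = dZ % Z % (1.0 - Z);

    const mat& x = X.slice(ti);
    g.Wz += x.t() * dZ_pre;  g.Wr += x.t() * dR_pre;
    g.Wh += x.t() * dHtl_pre;
    g.Uz += hprev.t() * dZ_pre; g.Ur += hprev.t() * dR_pre;
    g.Uh += (R % hprev).t() * dHtl_pre;
    g.bz += sum(dZ_pre, 0); g.br += sum(dR_pre, 0);
    g.bh += sum(dHtl_pre, 0);

    dhprev += dZ_pre * w.Uz.t() + dR_pre * w.Ur.t();
    dh = dhprev;
  }
}

struct HeadCache {
  cube Havg;    // B x U x T averaged per-position outputs
  cube A;       // B x A x T attention tanh pre-softmax features
  mat E;        // B x T attention logits
  mat alpha;    // B x T attention weights
  mat hbar;     // B x U averaged final hidden state
  mat ctx;      // B x U context vector
  cube P;       // B x K x T class probabilities
};

// Forward pass of the whole window model.  Fills caches; returns loss if
// Y is supplied (mean cross-entropy over B*T positions).
static double model_forward(const List& params, const cube& Xf,
                            const cube& Xr, const cube* Y,
                            GruCache& cf, GruCache& cr, HeadCache& hc) {
  GruWeights w = unpack_gru(params);
  mat Wa = Rcpp::as<mat>(params["Wa"]);   // U x A
  mat Ua = Rcpp::as<mat>(params["Ua"]);   // U x A
  rowvec ba = Rcpp::as<rowvec>(params["ba"]);
  colvec v = Rcpp::as<colvec>(params["v"]);
  mat Wd1 = Rcpp::as<mat>(params["Wd1"]); // U x K (per-position features)
  mat Wd2 = Rcpp::as<mat>(params["Wd2"]); // U x K (context features)
  rowvec bd = Rcpp::as<rowvec>(params["bd"]);

  const uword B = Xf.n_rows, T = Xf.n_slices;
  const uword U = w.Uz.n_rows, K = Wd1.n_cols, Adim = Wa.n_cols;

  gru_forward(Xf, w, cf);
  gru_forward(Xr, w, cr);

  hc.Havg.set_size(B, U, T);
  for (uword t = 0; t < T; ++t)
    hc.Havg.slice(t) = 0.5 * (cf.H.slice(t) + cr.H.slice(T - 1 - t));
  hc.hbar = 0.5 * (cf.H.slice(T - 1) + cr.H.slice(T - 1));

  // additive attention against the averaged final hidden state
  hc.A.set_size(B, Adim, T);
  hc.E.set_size(B, T);
  mat sh = hc.hbar * Ua + repmat(ba, B, 1);
  for (uword t = 0; t < T; ++t) {
    mat At = tanh(hc.Havg.slice(t) * Wa + sh);
    hc.A.slice(t) = At;
    hc.E.col(t) = At * v;
  }
  mat Em = hc.E.each_col() - max(hc.E, 1);
  hc.alpha = exp(Em);
  hc.alpha.each_col() /= sum(hc.alpha, 1);
  hc.ctx.zeros(B, U);
  for (uword t = 0; t < T; ++t)
    hc.ctx += hc.Havg.slice(t).each_col() % hc.alpha.col(t);

  hc.P.set_size(B, K, T);
  double loss = 0.0;
  mat ctxWd2 = hc.ctx * Wd2;
  for (uword t = 0; t < T; ++t) {
    mat logits = hc.Havg.slice(t) * Wd1 + ctxWd2 + repmat(bd, B, 1);
    logits.each_col() -= max(logits, 1);
    mat P = exp(logits);
    P.each_col() /= sum(P, 1);
    hc.P.slice(t) = P;
    if (Y != nullptr)
      loss -= accu(Y->slice(t) % log(P + 1e-12));
  }
  if (Y != nullptr) loss /= static_cast<double>(B * T);
  return loss;
}

// [[Rcpp::export]]
arma::cube cpp_nn_predict(Rcpp::List params, arma::cube Xf, arma::cube Xr) {
  GruCache cf, cr; HeadCache hc;
  model_forward(params, Xf, Xr, nullptr, cf, cr, hc);
  return hc.P;
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_loss_grad(Rcpp::List params, arma::cube Xf, arma::cube Xr,
                            arma::cube Y, bool want_grad = true) {
  GruCache cf, cr; HeadCache hc;
  double loss = model_forward(params, Xf, Xr, &Y, cf, cr, hc);
  if (!want_grad) return List::create(Named("loss") = loss);

  GruWeights w = unpack_gru(params);
  mat Wa = Rcpp::as<mat>(params["Wa"]);
  mat Ua = Rcpp::as<mat>(params["Ua"]);
  colvec v = Rcpp::as<colvec>(params["v"]);
  mat Wd1 = Rcpp::as<mat>(params["Wd1"]);
  mat Wd2 = Rcpp::as<mat>(params["Wd2"]);

  const uword B = Xf.n_rows, T = Xf.n_slices;
  const uword U = w.Uz.n_rows, K = Wd1.n_cols, Adim = Wa.n_cols;
  const double scale = 1.0 / static_cast<double>(B * T);

  mat gWa(U, Adim, fill::zeros), gUa(U, Adim, fill::zeros);
  rowvec gba(Adim, fill::zeros);
  colvec gv(Adim, fill::zeros);
  mat gWd1(U, K, fill::zeros), gWd2(U, K, fill::zeros);
  rowvec gbd(K, fill::zeros);

  cube dHavg(B, U, T, fill::zeros);
  mat dctx(B, U, fill::zeros);

  // dense softmax + cross-entropy
  for (uword t = 0; t < T; ++t) {
    mat dlog = (hc.P.slice(t) - Y.slice(t)) * scale;
    gWd1 += hc.Havg.slice(t).t() * dlog;
    gWd2 += hc.ctx.t() * dlog;
    gbd += sum(dlog, 0);
    dHavg.slice(t) += dlog * Wd1.t();
    dctx += dlog * Wd2.t();
  }

  // context: ctx = sum_t alpha_t * Havg_t
  mat dalpha(B, T, fill::none);
  for (uword t = 0; t < T; ++t) {
    dalpha.col(t) = sum(dctx % hc.Havg.slice(t), 1);
    dHavg.slice(t) += dctx.each_col() % hc.alpha.col(t);
  }
  // softmax over T (row-wise)
  colvec dot = sum(hc.alpha % dalpha, 1);
  mat dE = hc.alpha % (dalpha.each_col() - dot);

  mat dhbar(B, U, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    const mat& At = hc.A.slice(t);
    gv += At.t() * dE.col(t);
    mat dA_pre = (dE.col(t) * v.t()) % (1.0 - At % At);  // B x A
    dHavg.slice(t) += dA_pre * Wa.t();
    gWa += hc.Havg.slice(t).t() * dA_pre;
    gUa += hc.hbar.t() * dA_pre;
    gba += sum(dA_pre, 0);
    dhbar += dA_pre * Ua.t();
  }

  // split the averaged stream back to the two GRU passes
  cube dHf(B, U, T), dHr(B, U, T);
  for (uword t = 0; t < T; ++t) {
    dHf.slice(t) = 0.5 * dHavg.slice(t);
    dHr.slice(T - 1 - t) = 0.5 * dHavg.slice(t);
  }
  mat dhfin = 0.5 * dhbar;

  GruGrads g; g.init(Xf.n_cols, U);
  gru_backward(Xf, w, cf, dHf, dhfin, g);
  gru_backward(Xr, w, cr, dHr, dhfin, g);

  List grads = List::create(
    Named("Wz") = g.Wz, Named("Wr") = g.Wr, Named("Wh") = g.Wh,
    Named("Uz") = g.Uz, Named("Ur") = g.Ur, Named("Uh") = g.Uh,
    Named("bz") = g.bz, Named("br") = g.br, Named("bh") = g.bh,
    Named("Wa") = gWa, Named("Ua") = gUa, Named("ba") = gba,
    Named("v") = gv,
    Named("Wd1") = gWd1, Named("Wd2") = gWd2, Named("bd") = gbd);
  return List::create(Named("loss") = loss, Named("grads") = grads);
}
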