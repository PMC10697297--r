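// Compiled core of the longitudinal iterative block: batched BiLSTM +
// condensing layer forward and exact backward passes. Mirrors the pure-R
// reference implementation in R/nn.R (which the test suite uses as an
// oracle); dimensions are (batch, time, feature) arrays in column-major
// order, unpacked into per-step matrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// Unpack slice t of a (B, T, F) cube stored as arma::cube(B, T, F)
// (slice index = feature) into a B x F matrix.
static arma::mat step_of(const arma::cube& X, arma::uword t) {
  arma::mat out(X.n_rows, X.n_slices);
  for (arma::uword f = 0; f < X.n_slices; ++f) out.col(f) = X.slice(f).col(t);
  return out;
}

static void set_step(arma::cube& X, arma::uword t, const arma::mat& m) {
  for (arma::uword f = 0; f < X.n_slices; ++f) X.slice(f).col(t) = m.col(f);
}

struct LstmCache {
  std::vector<arma::mat> x, i, f, g, o, c_prev, h_prev, tc;
};

static void lstm_fwd(const arma::cube& X, const arma::mat& Wx,
                     const arma::mat& Wh, const arma::rowvec& b, bool reverse,
                     arma::cube& H, LstmCache& cc) {
  const arma::uword B = X.n_rows, T = X.n_cols, hd = Wh.n_rows;
  arma::mat h(B, hd, arma::fill::zeros), c(B, hd, arma::fill::zeros);
  cc.x.resize(T); cc.i.resize(T); cc.f.resize(T); cc.g.resize(T);
  cc.o.resize(T); cc.c_prev.resize(T); cc.h_prev.resize(T); cc.tc.resize(T);
  for (arma::uword s = 0; s < T; ++s) {
    arma::uword t = reverse ? (T - 1 - s) : s;
    arma::mat xt = step_of(X, t);
    arma::mat a = xt * Wx + h * Wh;
    a.each_row() += b;
    arma::mat ig = sigm(a.cols(0, hd - 1));
    arma::mat fg = sigm(a.cols(hd, 2 * hd - 1));
    arma::mat gg = arma::tanh(a.cols(2 * hd, 3 * hd - 1));
    arma::mat og = sigm(a.cols(3 * hd, 4 * hd - 1));
    arma::mat c_new = fg % c + ig % gg;
    arma::mat tc = arma::tanh(c_new);
    cc.x[s] = xt; cc.i[s] = ig; cc.f[s] = fg; cc.g[s] = gg; cc.o[s] = og;
    cc.c_prev[s] = c; cc.h_prev[s] = h; cc.tc[s] = tc;
    h = og % tc;
    c = c_new;
    set_step(H, t, h);
  }
}

// dH indexed by processing step s (already direction-ordered).
static void lstm_bwd(const std::vector<arma::mat>& dH, const LstmCache& cc,
                     const arma::mat& Wx, const arma::mat& Wh,
                     std::vector<arma::mat>& dX, arma::mat& dWx,
                     arma::mat& dWh, arma::rowvec& db) {
  const arma::uword T = dH.size(), hd = Wh.n_rows;
  const arma::uword B = cc.x[0].n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(4 * hd);
  dX.resize(T);
  arma::mat dh_next(B, hd, arma::fill::zeros), dc_next(B, hd, arma::fill::zeros);
  for (arma::uword s = T; s-- > 0;) {
    arma::mat dh = dH[s] + dh_next;
    arma::mat do_ = dh % cc.tc[s];
    arma::mat dc = dc_next + dh % cc.o[s] % (1.0 - arma::square(cc.tc[s]));
    arma::mat di = dc % cc.g[s];
    arma::mat dg = dc % cc.i[s];
    arma::mat df = dc % cc.c_prev[s];
    dc_next = dc % cc.f[s];
    arma::mat dA(B, 4 * hd);
    dA.cols(0, hd - 1) = di % cc.i[s] % (1.0 - cc.i[s]);
    dA.cols(hd, 2 * hd - 1) = df % cc.f[s] % (1.0 - cc.f[s]);
    dA.cols(2 * hd, 3 * hd - 1) = dg % (1.0 - arma::square(cc.g[s]));
    dA.cols(3 * hd, 4 * hd - 1) = do_ % cc.o[s] % (1.0 - cc.o[s]);
    dWx += cc.x[s].t() * dA;
    dWh += cc.h_prev[s].t() * dA;
    db += arma::sum(dA, 0);
    dX[s] = dA * Wx.t();
    dh_next = dA * Wh.t();
  }
}

// Forward through BiLSTM -> ReLU -> condensing affine -> ReLU. Returns the
// condensed cube plus everything backward needs, kept as an external
// pointer to avoid copying caches through R.
struct LibcCache {
  LstmCache fw, bw;
  arma::cube Hcat, R, Cpre;
  arma::uword B, T, F;
};

// [[Rcpp::export]]
List cpp_libc_fwd(const arma::cube& X, const arma::mat& f_Wx,
                  const arma::mat& f_Wh, const arma::rowvec& f_b,
                  const arma::mat& b_Wx, const arma::mat& b_Wh,
                  const arma::rowvec& b_b, const arma::mat& Wc,
                  const arma::rowvec& bc) {
  const arma::uword B = X.n_rows, T = X.n_cols, F = X.n_slices;
  const arma::uword hd = f_Wh.n_rows;
  XPtr<LibcCache> cache(new LibcCache(), true);
  arma::cube Hf(B, T, hd), Hb(B, T, hd);
  lstm_fwd(X, f_Wx, f_Wh, f_b, false, Hf, cache->fw);
  lstm_fwd(X, b_Wx, b_Wh, b_b, true, Hb, cache->bw);
  arma::cube Hcat(B, T, 2 * hd);
  for (arma::uword k = 0; k < hd; ++k) {
    Hcat.slice(k) = Hf.slice(k);
    Hcat.slice(hd + k) = Hb.slice(k);
  }
  arma::cube R = arma::clamp(Hcat, 0.0, arma::datum::inf);
  arma::cube Cpre(B, T, F), C(B, T, F);
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat rt = step_of(R, t);
    arma::mat ct = rt * Wc;
    ct.each_row() += bc;
    set_step(Cpre, t, ct);
    set_step(C, t, arma::clamp(ct, 0.0, arma::datum::inf));
  }
  cache->Hcat = Hcat;
  cache->R = R;
  cache->Cpre = Cpre;
  cache->B = B; cache->T = T; cache->F = F;
  return List::create(_["C"] = C, _["cache"] = cache);
}

// [[Rcpp::export]]
List cpp_libc_bwd(const arma::cube& dC, SEXP cache_ptr, const arma::mat& f_Wx,
                  const arma::mat& f_Wh, const arma::mat& b_Wx,
                  const arma::mat& b_Wh, const arma::mat& Wc) {
  XPtr<LibcCache> cache(cache_ptr);
  const arma::uword B = cache->B, T = cache->T, F = cache->F;
  const arma::uword hd = f_Wh.n_rows;
  arma::mat dWc(Wc.n_rows, Wc.n_cols, arma::fill::zeros);
  arma::rowvec dbc(F, arma::fill::zeros);
  arma::cube dR(B, T, 2 * hd);
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat dct = step_of(dC, t);
    arma::mat cpre = step_of(cache->Cpre, t);
    dct %= arma::conv_to<arma::mat>::from(cpre > 0.0);
    arma::mat rt = step_of(cache->R, t);
    dWc += rt.t() * dct;
    dbc += arma::sum(dct, 0);
    set_step(dR, t, dct * Wc.t());
  }
  for (arma::uword k = 0; k < 2 * hd; ++k) {
    dR.slice(k) %= arma::conv_to<arma::mat>::from(cache->Hcat.slice(k) > 0.0);
  }
  // forward direction: processing step s = time t
  std::vector<arma::mat> dHf(T), dHb(T);
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat mf(B, hd), mb(B, hd);
    for (arma::uword k = 0; k < hd; ++k) {
      mf.col(k) = dR.slice(k).col(t);
      mb.col(k) = dR.slice(hd + k).col(t);
    }
    dHf[t] = mf;
    dHb[T - 1 - t] = mb; // backward direction processed time T-1-s
  }
  std::vector<arma::mat> dXf, dXb;
  arma::mat dWxf, dWhf, dWxb, dWhb;
  arma::rowvec dbf, dbb;
  lstm_bwd(dHf, cache->fw, f_Wx, f_Wh, dXf, dWxf, dWhf, dbf);
  lstm_bwd(dHb, cache->bw, b_Wx, b_Wh, dXb, dWxb, dWhb, dbb);
  arma::cube dX(B, T, F, arma::fill::zeros);
  for (arma::uword s = 0; s < T; ++s) {
    // fw step s touched time s; bw step s touched time T-1-s
    arma::mat cur = step_of(dX, s);
    set_step(dX, s, cur + dXf[s]);
    arma::mat cur2 = step_of(dX, T - 1 - s);
    set_step(dX, T - 1 - s, cur2 + dXb[s]);
  }
  return List::create(
    _["dX"] = dX, _["f_Wx"] = dWxf, _["f_Wh"] = dWhf,
    _["f_b"] = arma::vec(dbf.t()), _["b_Wx"] = dWxb, _["b_Wh"] = dWhb,
    _["b_b"] = arma::vec(dbb.t()), _["Wc"] = dWc,
    _["bc"] = arma::vec(dbc.t()));
}
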