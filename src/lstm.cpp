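// LSTM layer forward pass and backpropagation-through-time.
//
// Layout conventions:
//   x  : arma::cube  (batch B) x (input dim D) x (time T)
//   Wx : D x 4H, Wh : H x 4H, b : 4H   -- gate blocks ordered i, f, g, o
//   hidden/cell sequences : B x H x T
// The input projection x_t * Wx is computed per slice; the recurrent
// projection h_{t-1} * Wh is the only sequential dependency.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& x, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b) {
  const uword B = x.n_rows, T = x.n_slices;
  const uword H = Wh.n_rows;
  if (Wx.n_rows != x.n_cols || Wx.n_cols != 4 * H || Wh.n_cols != 4 * H ||
      b.n_elem != 4 * H) {
    Rcpp::stop("lstm_forward_cpp: inconsistent parameter shapes");
  }
  cube Hs(B, H, T), Cs(B, H, T), G(B, 4 * H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  const rowvec br = b.t();

  for (uword t = 0; t < T; ++t) {
    mat z = x.slice(t) * Wx + h * Wh;
    z.each_row() += br;
    mat gi = sigmoid(z.cols(0, H - 1));
    mat gf = sigmoid(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat go = sigmoid(z.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    G.slice(t) = join_rows(join_rows(gi, gf), join_rows(gg, go));
    Cs.slice(t) = c;
    Hs.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs,
                            Rcpp::Named("G") = G);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& dH, const arma::cube& x,
                             const arma::cube& Hs, const arma::cube& Cs,
                             const arma::cube& G, const arma::mat& Wx,
                             const arma::mat& Wh, const bool need_dx) {
  const uword B = x.n_rows, D = x.n_cols, T = x.n_slices;
  const uword H = Wh.n_rows;

  mat dWx(D, 4 * H, fill::zeros), dWh(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  cube dX;
  if (need_dx) dX.set_size(B, D, T);

  for (uword tt = T; tt-- > 0;) {
    const mat gi = G.slice(tt).cols(0, H - 1);
    const mat gf = G.slice(tt).cols(H, 2 * H - 1);
    const mat gg = G.slice(tt).cols(2 * H, 3 * H - 1);
    const mat go = G.slice(tt).cols(3 * H, 4 * H - 1);
    const mat c = Cs.slice(tt);
    const mat c_prev = (tt > 0) ? Cs.slice(tt - 1) : mat(B, H, fill::zeros);
    const mat h_prev = (tt > 0) ? Hs.slice(tt - 1) : mat(B, H, fill::zeros);
    const mat tc = tanh(c);

    const mat dh = dH.slice(tt) + dh_next;
    const mat dgo = dh % tc;
    const mat dc = dc_next + dh % go % (1.0 - tc % tc);
    const mat dgi = dc % gg;
    const mat dgf = dc % c_prev;
    const mat dgg = dc % gi;

    const mat dzi = dgi % gi % (1.0 - gi);
    const mat dzf = dgf % gf % (1.0 - gf);
    const mat dzg = dgg % (1.0 - gg % gg);
    const mat dzo = dgo % go % (1.0 - go);
    const mat dz = join_rows(join_rows(dzi, dzf), join_rows(dzg, dzo));

    dWx += x.slice(tt).t() * dz;
    dWh += h_prev.t() * dz;
    db += sum(dz, 0);
    if (need_dx) dX.slice(tt) = dz * Wx.t();
    dh_next = dz * Wh.t();
    dc_next = dc % gf;
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dWx") = dWx, Rcpp::Named("dWh") = dWh,
      Rcpp::Named("db") = db.t());
  if (need_dx) out["dX"] = dX;
  return out;
}
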