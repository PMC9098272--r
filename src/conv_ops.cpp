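// Temporal filter-bank convolution in time-major layout: signals are
// (T x R) with one column per batch x electrode row, so sliding windows,
// im2col and the gemm all touch contiguous memory. "Same"-length padding:
// pad_left zeros before sample 1, K - 1 - pad_left after the last.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const uword BLOCK_COLS = 64;

static mat borrow(Rcpp::NumericMatrix& x) {
  return mat(x.begin(), x.nrow(), x.ncol(), false, true);
}

static cube borrow_cube(Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d[2], false, true);
}

static mat pad_rows(const mat& Xt, const uword K, const uword pad_left) {
  mat Xp(Xt.n_rows + K - 1, Xt.n_cols, fill::zeros);
  Xp.rows(pad_left, pad_left + Xt.n_rows - 1) = Xt;
  return Xp;
}

// im2col, time-major: P(j, t + T*(r - r0)) = Xp(t + j, r); every column of
// P is K consecutive doubles of Xp.
static void im2col_tblock(const mat& Xp, const uword r0, const uword nb,
                          const uword T, const uword K, mat& P) {
  for (uword r = 0; r < nb; ++r) {
    const double* src = Xp.colptr(r0 + r);
    double* dst = P.colptr(r * T);
    for (uword t = 0; t < T; ++t)
      std::memcpy(dst + t * K, src + t, K * sizeof(double));
  }
}

// Xt: T x R time-major signals; W: K x F kernels. Returns cube (T, R, F).
// [[Rcpp::export]]
Rcpp::NumericVector conv_time_fwd(Rcpp::NumericMatrix Xt,
                                  Rcpp::NumericMatrix W,
                                  const int pad_left) {
  mat Xm = borrow(Xt), Wm = borrow(W);
  const uword T = Xm.n_rows, R = Xm.n_cols, K = Wm.n_rows, F = Wm.n_cols;
  mat Xp = pad_rows(Xm, K, (uword)pad_left);
  Rcpp::NumericVector out_r(Rcpp::no_init(T * R * F));
  out_r.attr("dim") = Rcpp::IntegerVector::create(T, R, F);
  cube out = borrow_cube(out_r);
  mat P(K, BLOCK_COLS * T);
  for (uword r0 = 0; r0 < R; r0 += BLOCK_COLS) {
    const uword nb = std::min(BLOCK_COLS, R - r0);
    if (nb != BLOCK_COLS) P.set_size(K, nb * T);
    im2col_tblock(Xp, r0, nb, T, K, P);
    mat Yt = P.t() * Wm;                      // (nb*T) x F, t fastest
    for (uword f = 0; f < F; ++f)
      out.slice(f).cols(r0, r0 + nb - 1) = reshape(Yt.col(f), T, nb);
  }
  return out_r;
}

// G: cube (T, R, F) upstream gradient. Returns dW (K x F) and, when
// need_dx, dXt (T x R).
// [[Rcpp::export]]
Rcpp::List conv_time_bwd(Rcpp::NumericMatrix Xt, Rcpp::NumericVector G,
                         Rcpp::NumericMatrix W, const int pad_left,
                         const bool need_dx) {
  mat Xm = borrow(Xt), Wm = borrow(W);
  cube Gc = borrow_cube(G);
  const uword T = Xm.n_rows, R = Xm.n_cols, K = Wm.n_rows, F = Wm.n_cols;
  mat Xp = pad_rows(Xm, K, (uword)pad_left);
  Rcpp::NumericMatrix dW_r(K, F);
  mat dW = borrow(dW_r);
  mat dXp;
  if (need_dx) dXp.zeros(Xp.n_rows, Xp.n_cols);
  mat P(K, BLOCK_COLS * T), Gb(BLOCK_COLS * T, F);
  for (uword r0 = 0; r0 < R; r0 += BLOCK_COLS) {
    const uword nb = std::min(BLOCK_COLS, R - r0);
    if (nb != BLOCK_COLS) {
      P.set_size(K, nb * T);
      Gb.set_size(nb * T, F);
    }
    im2col_tblock(Xp, r0, nb, T, K, P);
    for (uword f = 0; f < F; ++f)
      Gb.col(f) = vectorise(Gc.slice(f).cols(r0, r0 + nb - 1));
    dW += P * Gb;                             // (K x nb*T)(nb*T x F)
    if (need_dx) {
      mat Q = Gb * Wm.t();                    // (nb*T) x K
      for (uword j = 0; j < K; ++j)
        dXp.submat(j, r0, j + T - 1, r0 + nb - 1) +=
            reshape(Q.col(j), T, nb);
    }
  }
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("dW") = dW_r);
  if (need_dx) {
    Rcpp::NumericMatrix dX_r(T, R);
    mat dX = borrow(dX_r);
    dX = dXp.rows(pad_left, pad_left + T - 1);
    res["dX"] = dX_r;
  }
  return res;
}
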