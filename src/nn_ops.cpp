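// Batch-norm kernels plus the fused batch-norm + depthwise-spatial-filter
// pair used on the block-1 tensor (time x batch*electrode x temporal map),
// the largest array in the network. The fused kernels make two passes over
// that tensor instead of materializing normalized copies. All R arrays are
// borrowed as aux-memory views (no conversion copies).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat borrow(Rcpp::NumericMatrix& x) {
  return mat(x.begin(), x.nrow(), x.ncol(), false, true);
}

static cube borrow_cube(Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d[2], false, true);
}

// x: n x F (feature-major columns). Training mode uses batch statistics and
// returns updated running statistics; eval mode standardizes with the
// stored ones.
// [[Rcpp::export]]
Rcpp::List bn_fwd_cpp(Rcpp::NumericMatrix x, Rcpp::NumericVector gamma,
                      Rcpp::NumericVector beta, Rcpp::NumericVector rmean,
                      Rcpp::NumericVector rvar, const bool training,
                      const double momentum, const double eps) {
  mat xm = borrow(x);
  const uword F = xm.n_cols, n = xm.n_rows;
  vec mu(F), v(F);
  if (training) {
    for (uword f = 0; f < F; ++f) {
      mu(f) = mean(xm.col(f));
      double acc = 0;
      const double* p = xm.colptr(f);
      for (uword i = 0; i < n; ++i) {
        const double d = p[i] - mu(f);
        acc += d * d;
      }
      v(f) = acc / n;  // biased, matching the normalization
    }
  } else {
    mu = vec(rmean.begin(), F);
    v = vec(rvar.begin(), F);
  }
  vec invstd = 1.0 / sqrt(v + eps);
  Rcpp::NumericVector out_r(Rcpp::no_init(n * F));
  out_r.attr("dim") = Rcpp::IntegerVector::create(n, F);
  mat out(out_r.begin(), n, F, false, true);
  for (uword f = 0; f < F; ++f)
    out.col(f) = (xm.col(f) - mu(f)) * (invstd(f) * gamma[f]) + beta[f];
  Rcpp::List res = Rcpp::List::create(
      Rcpp::Named("out") = out_r, Rcpp::Named("mu") = mu,
      Rcpp::Named("invstd") = invstd);
  if (training) {
    vec rm(rmean.begin(), F), rv(rvar.begin(), F);
    res["new_mean"] = vec((1.0 - momentum) * rm + momentum * mu);
    res["new_var"] = vec((1.0 - momentum) * rv + momentum * v);
  }
  return res;
}

// [[Rcpp::export]]
Rcpp::List bn_bwd_cpp(Rcpp::NumericMatrix g, Rcpp::NumericMatrix x,
                      Rcpp::NumericVector mu, Rcpp::NumericVector invstd,
                      Rcpp::NumericVector gamma, const bool training) {
  mat gm = borrow(g), xm = borrow(x);
  const uword F = gm.n_cols, n = gm.n_rows;
  Rcpp::NumericVector dgamma(F), dbeta(F);
  Rcpp::NumericMatrix dx_r(n, F);
  mat dx = borrow(dx_r);
  for (uword f = 0; f < F; ++f) {
    const double* gp = gm.colptr(f);
    const double* xp = xm.colptr(f);
    double dg = 0, db = 0;
    for (uword i = 0; i < n; ++i) {
      dg += gp[i] * (xp[i] - mu[f]) * invstd[f];
      db += gp[i];
    }
    dgamma[f] = dg;
    dbeta[f] = db;
    double* dp = dx.colptr(f);
    const double s = gamma[f] * invstd[f];
    if (training) {
      const double c1 = db / n, c2 = dg / n;
      for (uword i = 0; i < n; ++i)
        dp[i] = s * (gp[i] - c1 - (xp[i] - mu[f]) * invstd[f] * c2);
    } else {
      for (uword i = 0; i < n; ++i) dp[i] = s * gp[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx_r,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Fused batch norm + depthwise spatial filter, forward. z: cube (T, R, F)
// with column index r = b + B*(c-1); w: C x M spatial filters; parent:
// length-M 1-based temporal-map index per output map. Normalization is
// applied on the fly inside the electrode contraction, so no normalized
// copy of z is materialized. Returns out cube (T, B, M) plus the BN
// statistics.
// [[Rcpp::export]]
Rcpp::List bnspat_fwd(Rcpp::NumericVector z, Rcpp::NumericVector gamma,
                      Rcpp::NumericVector beta, Rcpp::NumericVector rmean,
                      Rcpp::NumericVector rvar, const bool training,
                      const double momentum, const double eps,
                      Rcpp::NumericMatrix w, Rcpp::IntegerVector parent,
                      const int B) {
  cube zc = borrow_cube(z);
  mat wm = borrow(w);
  const uword T = zc.n_rows, F = zc.n_slices, C = wm.n_rows, M = wm.n_cols;
  const uword n = T * zc.n_cols;
  vec mu(F), v(F);
  if (training) {
    for (uword f = 0; f < F; ++f) {
      const double* p = zc.slice_memptr(f);
      double s1 = 0, s2 = 0;
      for (uword i = 0; i < n; ++i) {
        s1 += p[i];
        s2 += p[i] * p[i];
      }
      mu(f) = s1 / n;
      v(f) = s2 / n - mu(f) * mu(f);
    }
  } else {
    mu = vec(rmean.begin(), F);
    v = vec(rvar.begin(), F);
  }
  vec invstd = 1.0 / sqrt(v + eps);
  Rcpp::NumericVector out_r(Rcpp::no_init(T * B * M));
  out_r.attr("dim") = Rcpp::IntegerVector::create(T, B, M);
  cube out = borrow_cube(out_r);
  out.zeros();
  for (uword m = 0; m < M; ++m) {
    const uword f = parent[m] - 1;
    const mat& zf = zc.slice(f);
    mat& ym = out.slice(m);
    const double scale = invstd(f) * gamma[f];
    const double shift = beta[f] - mu(f) * scale;
    for (uword c = 0; c < C; ++c) {
      const double a = wm(c, m) * scale;
      const double b = wm(c, m) * shift;
      ym += a * zf.cols(c * B, (c + 1) * B - 1) + b;
    }
  }
  Rcpp::List res = Rcpp::List::create(
      Rcpp::Named("out") = out_r, Rcpp::Named("mu") = mu,
      Rcpp::Named("invstd") = invstd);
  if (training) {
    vec rm(rmean.begin(), F), rv(rvar.begin(), F);
    res["new_mean"] = vec((1.0 - momentum) * rm + momentum * mu);
    res["new_var"] = vec((1.0 - momentum) * rv + momentum * v);
  }
  return res;
}

// Fused backward: gy is the gradient at the spatial-filter output
// (T, B, M). Two passes over z: one accumulating the BN reduction terms and
// the spatial-filter weight gradient, one emitting the pre-BN input
// gradient. Returns dz (T, R, F), dgamma, dbeta, dw.
// [[Rcpp::export]]
Rcpp::List bnspat_bwd(Rcpp::NumericVector z, Rcpp::NumericVector gy,
                      Rcpp::NumericVector mu, Rcpp::NumericVector invstd,
                      Rcpp::NumericVector gamma, Rcpp::NumericVector beta,
                      Rcpp::NumericMatrix w, Rcpp::IntegerVector parent,
                      const int B, const bool training) {
  cube zc = borrow_cube(z), gc = borrow_cube(gy);
  mat wm = borrow(w);
  const uword T = zc.n_rows, F = zc.n_slices, C = wm.n_rows, M = wm.n_cols;
  const uword n = T * zc.n_cols;
  Rcpp::NumericVector dgamma(F), dbeta(F);
  Rcpp::NumericMatrix dw_r(C, M);
  mat dw = borrow(dw_r);
  // children[f]: output maps fed by temporal map f
  std::vector<std::vector<uword>> children(F);
  for (uword m = 0; m < M; ++m) children[parent[m] - 1].push_back(m);
  const uword blk = (uword)T * B;
  for (uword f = 0; f < F; ++f) {
    const double scale = invstd[f] * gamma[f];
    const double shift = beta[f] - mu[f] * scale;
    const double inv = invstd[f];
    const double muf = mu[f];
    double dg = 0, db = 0;
    for (uword c = 0; c < C; ++c) {
      const double* zb = zc.slice_memptr(f) + c * blk;
      for (uword m : children[f]) {
        const double* gm = gc.slice_memptr(m);
        const double wcm = wm(c, m);
        double dwa = 0;
        for (uword i = 0; i < blk; ++i) {
          const double g = wcm * gm[i];
          db += g;
          dg += g * (zb[i] - muf) * inv;
          dwa += (scale * zb[i] + shift) * gm[i];
        }
        dw(c, m) = dwa;
      }
    }
    dgamma[f] = dg;
    dbeta[f] = db;
  }
  Rcpp::NumericVector dz_r(Rcpp::no_init(z.size()));
  dz_r.attr("dim") = z.attr("dim");
  cube dz = borrow_cube(dz_r);
  for (uword f = 0; f < F; ++f) {
    const double s = gamma[f] * invstd[f];
    const double inv = invstd[f];
    const double muf = mu[f];
    const double c1 = training ? dbeta[f] / n : 0.0;
    const double c2 = training ? dgamma[f] / n : 0.0;
    for (uword c = 0; c < C; ++c) {
      const double* zb = zc.slice_memptr(f) + c * blk;
      double* dzb = dz.slice_memptr(f) + c * blk;
      const std::vector<uword>& kids = children[f];
      if (kids.size() == 1) {
        const double* gm = gc.slice_memptr(kids[0]);
        const double wcm = wm(c, kids[0]);
        for (uword i = 0; i < blk; ++i)
          dzb[i] = s * (wcm * gm[i] - c1 - (zb[i] - muf) * inv * c2);
      } else {
        for (uword i = 0; i < blk; ++i) {
          double dn = 0;
          for (uword m : kids) dn += wm(c, m) * gc.slice_memptr(m)[i];
          dzb[i] = s * (dn - c1 - (zb[i] - muf) * inv * c2);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dz") = dz_r,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta,
                            Rcpp::Named("dw") = dw_r);
}

// Depthwise temporal convolution on (B, M, T): one length-K kernel per map,
// same-length zero padding (left K/2, right K/2 - 1 for even K).
// [[Rcpp::export]]
Rcpp::NumericVector dwconv_fwd_cpp(Rcpp::NumericVector x,
                                   Rcpp::NumericMatrix w) {
  Rcpp::IntegerVector d = x.attr("dim");
  const uword B = d[0], M = d[1], T = d[2], K = w.nrow();
  const uword pl = K / 2;
  Rcpp::NumericVector out_r(Rcpp::no_init(x.size()));
  out_r.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* op = out_r.begin();
  const uword plane = B * M;
  for (uword m = 0; m < M; ++m) {
    for (uword t = 0; t < T; ++t) {
      for (uword b = 0; b < B; ++b) {
        double acc = 0;
        // out[b,m,t] = sum_j x[b,m,t + j - pl] w[j,m]
        const uword j0 = (t < pl) ? pl - t : 0;
        const uword j1 = std::min(K, T + pl - t);
        for (uword j = j0; j < j1; ++j)
          acc += xp[b + m * B + (t + j - pl) * plane] * w(j, m);
        op[b + m * B + t * plane] = acc;
      }
    }
  }
  return out_r;
}

// [[Rcpp::export]]
Rcpp::List dwconv_bwd_cpp(Rcpp::NumericVector g, Rcpp::NumericVector x,
                          Rcpp::NumericMatrix w) {
  Rcpp::IntegerVector d = x.attr("dim");
  const uword B = d[0], M = d[1], T = d[2], K = w.nrow();
  const uword pl = K / 2;
  Rcpp::NumericVector dx_r(x.size());
  dx_r.attr("dim") = x.attr("dim");
  Rcpp::NumericMatrix dw_r(K, M);
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* dxp = dx_r.begin();
  const uword plane = B * M;
  for (uword m = 0; m < M; ++m) {
    for (uword t = 0; t < T; ++t) {
      const uword j0 = (t < pl) ? pl - t : 0;
      const uword j1 = std::min(K, T + pl - t);
      for (uword b = 0; b < B; ++b) {
        const double gv = gp[b + m * B + t * plane];
        for (uword j = j0; j < j1; ++j) {
          const uword src = b + m * B + (t + j - pl) * plane;
          dxp[src] += gv * w(j, m);
          dw_r(j, m) += gv * xp[src];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx_r,
                            Rcpp::Named("dw") = dw_r);
}
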