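// Compiled kernels for the convolutional layers. Tensors arrive as numeric
// vectors with dim [channel, lead, time, batch] (channel fastest); per-batch
// Armadillo matrix views make the temporal convolutions a handful of small
// GEMMs with no intermediate copies. The pure-R reference implementations in
// R/nn.R compute the same quantities and are compared against these in the
// test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static IntegerVector dims_of(const NumericVector& x) {
  return x.attr("dim");
}

// [[Rcpp::export]]
List conv_time_fwd_cpp(NumericVector x, NumericVector W, NumericVector b) {
  IntegerVector dx = dims_of(x), dw = dims_of(W);
  const int Ci = dx[0], L = dx[1], T = dx[2], N = dx[3];
  const int Co = dw[0], K = dw[2], pad = (K - 1) / 2, Tp = T + K - 1;
  NumericVector xp((size_t)Ci * L * Tp * N);
  NumericVector out((size_t)Co * L * T * N);
  for (int n = 0; n < N; ++n) {
    arma::mat x_n(x.begin() + (size_t)n * Ci * L * T, Ci, L * T, false);
    arma::mat xp_n(xp.begin() + (size_t)n * Ci * L * Tp, Ci, L * Tp, false, true);
    xp_n.cols(L * pad, L * pad + L * T - 1) = x_n;
  }
  // one GEMM per tap over the whole padded batch; the tap-shifted reads that
  // cross a sample boundary only pollute padded output columns, which are
  // dropped on extraction. Pointer-alias matrices keep every GEMM operand a
  // plain contiguous Mat (no subview temporaries).
  const size_t ncol_full = (size_t)L * Tp * N;
  const size_t ncol_used = ncol_full - (size_t)L * (K - 1);
  std::vector<double> opad(Co * ncol_full, 0.0);
  for (int k = 0; k < K; ++k) {
    arma::mat Wk(W.begin() + (size_t)k * Co * Ci, Co, Ci, false);
    arma::mat xs(xp.begin() + (size_t)Ci * L * k, Ci, ncol_used, false);
    arma::mat os(opad.data(), Co, ncol_used, false, true);
    os += Wk * xs;
  }
  arma::mat opad_m(opad.data(), Co, ncol_full, false);
  arma::vec bv(b.begin(), Co, false);
  for (int n = 0; n < N; ++n) {
    arma::mat out_n(out.begin() + (size_t)n * Co * L * T, Co, L * T, false, true);
    out_n = opad_m.cols((size_t)n * L * Tp, (size_t)n * L * Tp + L * T - 1);
    out_n.each_col() += bv;
  }
  out.attr("dim") = IntegerVector::create(Co, L, T, N);
  xp.attr("dim") = IntegerVector::create(Ci, L, Tp, N);
  return List::create(_["out"] = out, _["xp"] = xp);
}

// [[Rcpp::export]]
List conv_time_bwd_cpp(NumericVector dout, NumericVector xp, NumericVector W) {
  IntegerVector dd = dims_of(dout), dp = dims_of(xp), dw = dims_of(W);
  const int Co = dd[0], L = dd[1], T = dd[2], N = dd[3];
  const int Ci = dp[0], K = dw[2], pad = (K - 1) / 2, Tp = dp[2];
  NumericVector dW(Co * Ci * K), db(Co), dx((size_t)Ci * L * T * N);
  const size_t ncol_full = (size_t)L * Tp * N;
  const size_t ncol_used = ncol_full - (size_t)L * (K - 1);
  // place dout into a time-padded buffer at tau in [0, T); its padded tail
  // columns are zero, so tap-shifted GEMMs cannot pollute across samples
  std::vector<double> dop(Co * ncol_full, 0.0);
  arma::mat dop_m(dop.data(), Co, ncol_full, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat dout_n(dout.begin() + (size_t)n * Co * L * T, Co, L * T, false);
    dop_m.cols((size_t)n * L * Tp, (size_t)n * L * Tp + L * T - 1) = dout_n;
  }
  std::vector<double> dxp(Ci * ncol_full, 0.0);
  arma::mat xp_m(xp.begin(), Ci, ncol_full, false);
  for (int k = 0; k < K; ++k) {
    arma::mat dWk(dW.begin() + (size_t)k * Co * Ci, Co, Ci, false, true);
    arma::mat Wk(W.begin() + (size_t)k * Co * Ci, Co, Ci, false);
    arma::mat dops(dop.data(), Co, ncol_used, false);
    arma::mat xs(xp.begin() + (size_t)Ci * L * k, Ci, ncol_used, false);
    arma::mat dxs(dxp.data() + (size_t)Ci * L * k, Ci, ncol_used, false, true);
    dWk = dops * xs.t();
    dxs += Wk.t() * dops;
  }
  arma::vec dbv(db.begin(), Co, false, true);
  dbv = arma::sum(dop_m, 1);
  for (int n = 0; n < N; ++n) {
    arma::mat dx_n(dx.begin() + (size_t)n * Ci * L * T, Ci, L * T, false, true);
    arma::mat dxp_n(dxp.data() + (size_t)n * Ci * L * Tp, Ci, L * Tp, false);
    dx_n = dxp_n.cols(L * pad, L * pad + L * T - 1);
  }
  dW.attr("dim") = IntegerVector::create(Co, Ci, K);
  dx.attr("dim") = IntegerVector::create(Ci, L, T, N);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List deconv_out_fwd_cpp(NumericVector h, NumericVector W, NumericVector b_lead) {
  IntegerVector dh = dims_of(h), dw = dims_of(W);
  const int C = dh[0], L = dh[1], Tc = dh[2], N = dh[3];
  const int f = dw[1], J = dw[2], Tp = Tc + J - 1;
  NumericVector hp(C * L * Tp * N);
  NumericVector out(L * f * Tc * N);
  for (int n = 0; n < N; ++n) {
    arma::mat h_n(h.begin() + (size_t)n * C * L * Tc, C, L * Tc, false);
    arma::mat hp_n(hp.begin() + (size_t)n * C * L * Tp, C, L * Tp, false, true);
    hp_n.cols(0, L * Tc - 1) = h_n;
  }
  const double* Wp = W.begin();
  const double* hpp = hp.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < Tc; ++t) {
      for (int p = 0; p < f; ++p) {
        for (int l = 0; l < L; ++l) {
          double acc = b_lead[l];
          for (int j = 0; j < J; ++j) {
            const double* hcol = hpp + (size_t)C * (l + (size_t)L * ((t + j) + (size_t)Tp * n));
            const double* wcol = Wp + (size_t)C * (p + (size_t)f * j);
            for (int c = 0; c < C; ++c) acc += wcol[c] * hcol[c];
          }
          op[l + (size_t)L * (p + (size_t)f * (t + (size_t)Tc * n))] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(L, f * Tc, N);
  hp.attr("dim") = IntegerVector::create(C, L, Tp, N);
  return List::create(_["out"] = out, _["hp"] = hp);
}

// [[Rcpp::export]]
List deconv_out_bwd_cpp(NumericVector dout, NumericVector hp, NumericVector W) {
  IntegerVector dd = dims_of(dout), dph = dims_of(hp), dw = dims_of(W);
  const int L = dd[0], N = dd[2];
  const int C = dph[0], Tp = dph[2];
  const int f = dw[1], J = dw[2], Tc = Tp - J + 1;
  NumericVector dW(C * f * J), db_lead(L), dh(C * L * Tc * N);
  NumericVector dhp(C * L * Tp * N);
  const double* dop = dout.begin();
  const double* hpp = hp.begin();
  const double* Wp = W.begin();
  double* dWp = dW.begin();
  double* dhpp = dhp.begin();
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < Tc; ++t) {
      for (int p = 0; p < f; ++p) {
        for (int l = 0; l < L; ++l) {
          const double g = dop[l + (size_t)L * (p + (size_t)f * (t + (size_t)Tc * n))];
          db_lead[l] += g;
          for (int j = 0; j < J; ++j) {
            const size_t hoff = (size_t)C * (l + (size_t)L * ((t + j) + (size_t)Tp * n));
            const size_t woff = (size_t)C * (p + (size_t)f * j);
            for (int c = 0; c < C; ++c) {
              dWp[woff + c] += g * hpp[hoff + c];
              dhpp[hoff + c] += g * Wp[woff + c];
            }
          }
        }
      }
    }
  }
  for (int n = 0; n < N; ++n) {
    arma::mat dhp_n(dhp.begin() + (size_t)n * C * L * Tp, C, L * Tp, false);
    arma::mat dh_n(dh.begin() + (size_t)n * C * L * Tc, C, L * Tc, false, true);
    dh_n = dhp_n.cols(0, L * Tc - 1);
  }
  dW.attr("dim") = IntegerVector::create(C, f, J);
  dh.attr("dim") = IntegerVector::create(C, L, Tc, N);
  return List::create(_["dh"] = dh, _["dW"] = dW, _["db_lead"] = db_lead);
}

// [[Rcpp::export]]
NumericVector elu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* xi = x.begin(); double* yi = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yi[i] = xi[i] > 0 ? xi[i] : expm1(xi[i]);
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector elu_bwd_cpp(NumericVector dy, NumericVector y) {
  NumericVector g(dy.size());
  const double* d = dy.begin(); const double* yi = y.begin();
  double* gi = g.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    gi[i] = yi[i] >= 0 ? d[i] : d[i] * (yi[i] + 1.0);
  g.attr("dim") = dy.attr("dim");
  return g;
}

// x: [C, L, T, N] -> [C, L, T/f, N], mean over consecutive time groups
// [[Rcpp::export]]
NumericVector pool_time_fwd_cpp(NumericVector x, int f) {
  IntegerVector d = dims_of(x);
  const R_xlen_t CL = (R_xlen_t)d[0] * d[1], M = ((R_xlen_t)d[2] / f) * d[3];
  NumericVector out(CL * M);
  const double* xi = x.begin(); double* oi = out.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* blk = xi + m * CL * f;
    double* ob = oi + m * CL;
    for (int p = 0; p < f; ++p)
      for (R_xlen_t c = 0; c < CL; ++c) ob[c] += blk[p * CL + c];
    for (R_xlen_t c = 0; c < CL; ++c) ob[c] /= f;
  }
  out.attr("dim") = IntegerVector::create(d[0], d[1], d[2] / f, d[3]);
  return out;
}

// [[Rcpp::export]]
NumericVector pool_time_bwd_cpp(NumericVector dout, int f) {
  IntegerVector d = dims_of(dout);
  const R_xlen_t CL = (R_xlen_t)d[0] * d[1], M = (R_xlen_t)d[2] * d[3];
  NumericVector dx(CL * f * M);
  const double* di = dout.begin(); double* xi = dx.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* db = di + m * CL;
    double* blk = xi + m * CL * f;
    for (int p = 0; p < f; ++p)
      for (R_xlen_t c = 0; c < CL; ++c) blk[p * CL + c] = db[c] / f;
  }
  dx.attr("dim") = IntegerVector::create(d[0], d[1], d[2] * f, d[3]);
  return dx;
}

// [[Rcpp::export]]
NumericVector upsample_time_fwd_cpp(NumericVector x, int f) {
  IntegerVector d = dims_of(x);
  const R_xlen_t CL = (R_xlen_t)d[0] * d[1], M = (R_xlen_t)d[2] * d[3];
  NumericVector out(CL * f * M);
  const double* xi = x.begin(); double* oi = out.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xb = xi + m * CL;
    double* blk = oi + m * CL * f;
    for (int p = 0; p < f; ++p)
      for (R_xlen_t c = 0; c < CL; ++c) blk[p * CL + c] = xb[c];
  }
  out.attr("dim") = IntegerVector::create(d[0], d[1], d[2] * f, d[3]);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample_time_bwd_cpp(NumericVector dout, int f) {
  IntegerVector d = dims_of(dout);
  const R_xlen_t CL = (R_xlen_t)d[0] * d[1], M = ((R_xlen_t)d[2] / f) * d[3];
  NumericVector dx(CL * M);
  const double* di = dout.begin(); double* xi = dx.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* blk = di + m * CL * f;
    double* xb = xi + m * CL;
    for (int p = 0; p < f; ++p)
      for (R_xlen_t c = 0; c < CL; ++c) xb[c] += blk[p * CL + c];
  }
  dx.attr("dim") = IntegerVector::create(d[0], d[1], d[2] / f, d[3]);
  return dx;
}

// Batch normalization over channels (first dim), fused two-pass version.
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector run_mean, NumericVector run_var, bool training,
                double momentum, double eps) {
  IntegerVector d = dims_of(x);
  const int C = d[0];
  const R_xlen_t M = x.size() / C;
  NumericVector mu(C), var(C), istd(C), out(x.size());
  NumericVector rm = clone(run_mean), rv = clone(run_var);
  const double* xi = x.begin();
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  if (training) {
    for (R_xlen_t m = 0; m < M; ++m) {
      const double* col = xi + m * C;
      for (int c = 0; c < C; ++c) { s1[c] += col[c]; s2[c] += col[c] * col[c]; }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = s1[c] / M;
      var[c] = s2[c] / M - mu[c] * mu[c];
      rm[c] = (1 - momentum) * rm[c] + momentum * mu[c];
      rv[c] = (1 - momentum) * rv[c] + momentum * var[c];
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = run_mean[c]; var[c] = run_var[c]; }
  }
  // fold the affine transform into one scale/shift per channel
  std::vector<double> a(C), bsh(C), is(C);
  for (int c = 0; c < C; ++c) {
    is[c] = 1.0 / sqrt(var[c] + eps);
    istd[c] = is[c];
    a[c] = gamma[c] * is[c];
    bsh[c] = beta[c] - a[c] * mu[c];
  }
  double* oi = out.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* col = xi + m * C;
    double* oc = oi + m * C;
    for (int c = 0; c < C; ++c) oc[c] = a[c] * col[c] + bsh[c];
  }
  out.attr("dim") = x.attr("dim");
  return List::create(_["out"] = out, _["mu"] = mu, _["istd"] = istd,
                      _["run_mean"] = rm, _["run_var"] = rv);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dout, NumericVector x, NumericVector mu,
                NumericVector istd, NumericVector gamma) {
  const int C = dims_of(dout)[0];
  const R_xlen_t M = dout.size() / C;
  NumericVector dgamma(C), dbeta(C), dx(dout.size());
  const double* di = dout.begin(); const double* xi = x.begin();
  std::vector<double> sg(C, 0.0), sb(C, 0.0), muv(C), isv(C), gv(C);
  for (int c = 0; c < C; ++c) { muv[c] = mu[c]; isv[c] = istd[c]; gv[c] = gamma[c]; }
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* dc = di + m * C;
    const double* xc = xi + m * C;
    for (int c = 0; c < C; ++c) {
      sg[c] += dc[c] * (xc[c] - muv[c]) * isv[c];
      sb[c] += dc[c];
    }
  }
  std::vector<double> s1(C), s2(C);
  for (int c = 0; c < C; ++c) {
    dgamma[c] = sg[c];
    dbeta[c] = sb[c];
    s1[c] = gv[c] * sb[c] / M;            // mean of dxhat
    s2[c] = gv[c] * sg[c] / M;            // mean of dxhat * xhat
  }
  double* dxi = dx.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* dc = di + m * C;
    const double* xc = xi + m * C;
    double* oc = dxi + m * C;
    for (int c = 0; c < C; ++c) {
      const double xh = (xc[c] - muv[c]) * isv[c];
      oc[c] = isv[c] * (gv[c] * dc[c] - s1[c] - xh * s2[c]);
    }
  }
  dx.attr("dim") = dout.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
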