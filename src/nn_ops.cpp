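// Convolution forward/backward via im2col + GEMM.
//
// Tensor layout everywhere: column-major R arrays
//   activations  (H, W, C, N)   -- height fastest
//   kernels      (kh, kw, Cin, Cout)
// so the first three dims of a kernel flatten contiguously into the
// im2col row index i + kh*(j + kw*c).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pt, int pl,
                       int Ho, int Wo, arma::mat& col, int col_off) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride + j - pl;
          const bool wok = (wsrc >= 0 && wsrc < W);
          double* dst = col.colptr(col_off + (size_t)wo * Ho) + row;
          for (int ho = 0; ho < Ho; ++ho, dst += col.n_rows) {
            const int hsrc = ho * stride + i - pt;
            *dst = (wok && hsrc >= 0 && hsrc < H)
                     ? xc[hsrc + (size_t)H * wsrc] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& col, int col_off,
                       double* gx, int H, int W, int C,
                       int kh, int kw, int stride, int pt, int pl,
                       int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride + j - pl;
          if (wsrc < 0 || wsrc >= W) continue;
          const double* src = col.colptr(col_off + (size_t)wo * Ho) + row;
          for (int ho = 0; ho < Ho; ++ho, src += col.n_rows) {
            const int hsrc = ho * stride + i - pt;
            if (hsrc >= 0 && hsrc < H)
              gc[hsrc + (size_t)H * wsrc] += *src;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, IntegerVector xd,
                          NumericVector w, IntegerVector wd,
                          NumericVector b, int stride,
                          int pt, int pl, int pb, int pr) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cin);
  const int Ho = (H + pt + pb - kh) / stride + 1;
  const int Wo = (W + pl + pr - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty (input %dx%d)", H, W);
  const int K = kh * kw * Cin;

  arma::mat col(K, (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pt, pl, Ho, Wo, col, (size_t)Ho * Wo * n);

  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat out_mat = Wm.t() * col;  // Cout x (Ho*Wo*N)

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      double* dst = op + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (int p = 0; p < Ho * Wo; ++p)
        dst[p] = out_mat(co, (size_t)Ho * Wo * n + p) + bias;
    }
  return out;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, IntegerVector xd,
                 NumericVector w, IntegerVector wd,
                 NumericVector gout, int stride,
                 int pt, int pl, int pb, int pr) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = (H + pt + pb - kh) / stride + 1;
  const int Wo = (W + pl + pr - kw) / stride + 1;
  const int K = kh * kw * Cin;

  arma::mat col(K, (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pt, pl, Ho, Wo, col, (size_t)Ho * Wo * n);

  // permute gout (Ho,Wo,Cout,N) -> Cout x (Ho*Wo*N)
  arma::mat gout_mat(Cout, (size_t)Ho * Wo * N);
  const double* gp = gout.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = gp + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (int p = 0; p < Ho * Wo; ++p)
        gout_mat(co, (size_t)Ho * Wo * n + p) = src[p];
    }

  arma::mat gW = col * gout_mat.t();            // K x Cout
  arma::vec gb = arma::sum(gout_mat, 1);        // Cout
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gcol = Wm * gout_mat;               // K x (Ho*Wo*N)

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  std::fill(gx.begin(), gx.end(), 0.0);
  for (int n = 0; n < N; ++n)
    col2im_one(gcol, (size_t)Ho * Wo * n,
               gx.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pt, pl, Ho, Wo);

  NumericVector gw(gW.memptr(), gW.memptr() + gW.n_elem);
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// ---- conv with cached im2col -----------------------------------------------

// [[Rcpp::export]]
List nn_conv_fwd_cache(NumericVector x, IntegerVector xd,
                       NumericVector w, IntegerVector wd,
                       NumericVector b, int stride,
                       int pt, int pl, int pb, int pr) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cin);
  const int Ho = (H + pt + pb - kh) / stride + 1;
  const int Wo = (W + pl + pr - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty (input %dx%d)", H, W);
  const int K = kh * kw * Cin;

  NumericMatrix colR(K, Ho * Wo * N);
  arma::mat col(colR.begin(), K, (size_t)Ho * Wo * N, false, true);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pt, pl, Ho, Wo, col, (size_t)Ho * Wo * n);

  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat out_mat = Wm.t() * col;

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      double* dst = op + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (int p = 0; p < Ho * Wo; ++p)
        dst[p] = out_mat(co, (size_t)Ho * Wo * n + p) + bias;
    }
  return List::create(_["out"] = out, _["col"] = colR);
}

// [[Rcpp::export]]
List nn_conv_bwd_cached(NumericMatrix colR, IntegerVector xd,
                        NumericVector w, IntegerVector wd,
                        NumericVector gout, int stride,
                        int pt, int pl, int pb, int pr, bool need_gx) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + pt + pb - kh) / stride + 1;
  const int Wo = (W + pl + pr - kw) / stride + 1;
  const int K = kh * kw * wd[2];
  const arma::mat col(colR.begin(), K, (size_t)Ho * Wo * N, false, true);

  arma::mat gout_mat(Cout, (size_t)Ho * Wo * N);
  const double* gp = gout.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = gp + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (int p = 0; p < Ho * Wo; ++p)
        gout_mat(co, (size_t)Ho * Wo * n + p) = src[p];
    }

  arma::mat gW = col * gout_mat.t();
  arma::vec gb = arma::sum(gout_mat, 1);
  NumericVector gw(gW.memptr(), gW.memptr() + gW.n_elem);
  gw.attr("dim") = wd;

  if (!need_gx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw,
                        _["gb"] = NumericVector(gb.begin(), gb.end()));

  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gcol = Wm * gout_mat;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  std::fill(gx.begin(), gx.end(), 0.0);
  for (int n = 0; n < N; ++n)
    col2im_one(gcol, (size_t)Ho * Wo * n,
               gx.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pt, pl, Ho, Wo);
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// ---- batch norm -------------------------------------------------------------

// per-channel mean and biased variance over (H, W, N)
// [[Rcpp::export]]
List nn_bn_stats(NumericVector x, IntegerVector xd) {
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector mu(C), va(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + (size_t)HW * (c + (size_t)C * n);
      for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    mu[c] = s / m;
    va[c] = std::max(s2 / m - mu[c] * mu[c], 0.0);
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// out = gamma * xhat + beta, xhat = (x - mu) * istd
// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, IntegerVector xd,
               NumericVector gamma, NumericVector beta,
               NumericVector mu, NumericVector istd) {
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector out(no_init(x.size())), xhat(no_init(x.size()));
  out.attr("dim") = xd; xhat.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double* xh = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      double* o = out.begin() + (size_t)HW * (c + (size_t)C * n);
      const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
      for (int i = 0; i < HW; ++i) {
        xh[i] = (p[i] - m) * is;
        o[i] = g * xh[i] + b;
      }
    }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// [[Rcpp::export]]
List nn_bn_bwd(NumericVector xhat, IntegerVector xd, NumericVector gout,
               NumericVector gamma, NumericVector istd, bool training) {
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector ggamma(C), gbeta(C), gin(no_init(xhat.size()));
  gin.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* go = gout.begin() + (size_t)HW * (c + (size_t)C * n);
      const double* xh = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      for (int i = 0; i < HW; ++i) { s1 += go[i]; s2 += go[i] * xh[i]; }
    }
    gbeta[c] = s1; ggamma[c] = s2;
    const double g = gamma[c], is = istd[c];
    const double gs1 = g * s1 / m, gs2 = g * s2 / m;
    for (int n = 0; n < N; ++n) {
      const double* go = gout.begin() + (size_t)HW * (c + (size_t)C * n);
      const double* xh = xhat.begin() + (size_t)HW * (c + (size_t)C * n);
      double* gi = gin.begin() + (size_t)HW * (c + (size_t)C * n);
      if (training)
        for (int i = 0; i < HW; ++i) gi[i] = (g * go[i] - gs1 - xh[i] * gs2) * is;
      else
        for (int i = 0; i < HW; ++i) gi[i] = g * go[i] * is;
    }
  }
  return List::create(_["gin"] = gin, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---- relu -------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector nn_relu_fwd(NumericVector x) {
  NumericVector out(no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  return out;
}

// gradient through relu using the forward output (out > 0 <=> x > 0)
// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector out, NumericVector gout) {
  NumericVector gin(no_init(out.size()));
  gin.attr("dim") = gout.attr("dim");
  const double* op = out.begin();
  const double* gp = gout.begin();
  double* ip = gin.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) ip[i] = op[i] > 0 ? gp[i] : 0.0;
  return gin;
}
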