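// Compiled kernels for the classifier harness: same-padding stride-1
// convolution (im2col + BLAS GEMM) and max pooling, both operating on
// (H, W, N, C) column-major arrays (batch before channels, so a
// convolution's output is already in the layout the next layer consumes).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for a zero-padded same convolution: returns (kh*kw*C, H*W*N),
// column order (oi fast, oj, n), row order (dh fast, dw, c)
static arma::mat im2col_same(const double* x, int H, int W, int N, int C,
                             int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int k2c = kh * kw * C;
  const long HWN = (long)H * W * N;
  arma::mat cols(k2c, HWN, arma::fill::zeros);
  const long planeHW = (long)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (long)c * planeHW * N;
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (long)n * planeHW;
      for (int oj = 0; oj < W; ++oj) {
        for (int oi = 0; oi < H; ++oi) {
          const long colidx = oi + (long)H * oj + (long)H * W * n;
          double* dst = cols.colptr(colidx) + (long)c * kh * kw;
          for (int dw = 0; dw < kw; ++dw) {
            const int sj = oj + dw - pw;
            if (sj < 0 || sj >= W) { dst += kh; continue; }
            const double* src = xn + (long)H * sj;
            for (int dh = 0; dh < kh; ++dh) {
              const int si = oi + dh - ph;
              *dst++ = (si < 0 || si >= H) ? 0.0 : src[si];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(const NumericVector& x, int H, int W, int N,
                               int C, const arma::mat& Wt,
                               const arma::vec& b, int kh, int kw,
                               bool relu) {
  arma::mat cols = im2col_same(x.begin(), H, W, N, C, kh, kw);
  const int F = Wt.n_cols;
  arma::mat out = cols.t() * Wt;            // (H*W*N, F)
  out.each_row() += b.t();
  if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, N, F);
  return res;
}

// [[Rcpp::export]]
List cpp_conv_backward(const NumericVector& x, int H, int W, int N, int C,
                       const arma::mat& Wt, int kh, int kw,
                       const NumericVector& dout, const NumericVector& out,
                       bool relu, bool need_input_grad) {
  const int F = Wt.n_cols;
  const long HWN = (long)H * W * N;
  arma::mat dz(HWN, F);
  std::copy(dout.begin(), dout.end(), dz.memptr());
  if (relu) {
    const double* o = out.begin();
    double* d = dz.memptr();
    const long tot = HWN * F;
    for (long i = 0; i < tot; ++i) if (o[i] <= 0.0) d[i] = 0.0;
  }
  arma::mat cols = im2col_same(x.begin(), H, W, N, C, kh, kw);
  arma::mat dWt = cols * dz;                // (k2c, F)
  arma::rowvec db = arma::sum(dz, 0);
  List res = List::create(Named("dWt") = dWt,
                          Named("db") = NumericVector(db.begin(), db.end()),
                          Named("dx") = R_NilValue);
  if (need_input_grad) {
    arma::mat dcols = Wt * dz.t();          // (k2c, H*W*N)
    const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
    NumericVector dxv((long)H * W * N * C);
    double* dx = dxv.begin();
    const long planeHW = (long)H * W;
    for (int c = 0; c < C; ++c) {
      double* dxc = dx + (long)c * planeHW * N;
      for (int n = 0; n < N; ++n) {
        double* dxn = dxc + (long)n * planeHW;
        for (int oj = 0; oj < W; ++oj) {
          for (int oi = 0; oi < H; ++oi) {
            const long colidx = oi + (long)H * oj + (long)H * W * n;
            const double* src = dcols.colptr(colidx);
            for (int dw = 0; dw < kw; ++dw) {
              const int sj = oj + dw - pw;
              if (sj < 0 || sj >= W) continue;
              for (int dh = 0; dh < kh; ++dh) {
                const int si = oi + dh - ph;
                if (si < 0 || si >= H) continue;
                dxn[si + (long)H * sj] +=
                  src[(long)c * kh * kw + dw * kh + dh];
              }
            }
          }
        }
      }
    }
    dxv.attr("dim") = IntegerVector::create(H, W, N, C);
    res["dx"] = dxv;
  }
  return res;
}

// (ph x pw) max pooling with stride = window, floor semantics; argmax is
// the 1-based linear index into x (ties resolve to the first element in
// column-major window order)
// [[Rcpp::export]]
List cpp_maxpool_forward(const NumericVector& x, int H, int W, int N, int C,
                         int ph, int pw) {
  const int Ho = H / ph, Wo = W / pw;
  const long n_out = (long)Ho * Wo * N * C;
  NumericVector out(n_out);
  IntegerVector arg(n_out);
  const double* xp = x.begin();
  long k = 0;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const long base_nc = (long)H * W * (n + (long)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300;
          long besti = -1;
          for (int dw = 0; dw < pw; ++dw) {
            const long col = base_nc + (long)H * (wo * pw + dw);
            for (int dh = 0; dh < ph; ++dh) {
              const long idx = col + ho * ph + dh;
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          out[k] = best;
          arg[k] = (int)(besti + 1);
          ++k;
        }
      }
    }
  }
  // out was filled in (ho fast, wo, n, c) order == column-major (Ho,Wo,N,C)
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(Named("out") = out, Named("argmax") = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(const NumericVector& dout,
                                   const IntegerVector& argmax, int len_x) {
  NumericVector dx(len_x);
  const int n = dout.size();
  for (int i = 0; i < n; ++i) dx[argmax[i] - 1] += dout[i];
  return dx;
}
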