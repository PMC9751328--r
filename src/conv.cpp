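// Minimal conv-net kernels: 3x3-style "same" convolution and 2x2 max pooling,
// forward and backward, over batched single/multi-channel images laid out as
// R arrays [H, W, C, B] (column-major, H fastest). im2col + BLAS matmul.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double* x, int H, int W, int Cin,
                        int kh, int kw, int pad, int Ho, int Wo) {
  arma::mat Xc(kh * kw * Cin, Ho * Wo, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (std::size_t)ci * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo + j - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          const double* col = xc + (std::size_t)wsrc * H;
          double* dst = Xc.colptr(Ho * wo) + r;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho + i - pad;
            if (hsrc < 0 || hsrc >= H) continue;
            dst[(std::size_t)ho * Xc.n_rows] = col[hsrc];
          }
        }
      }
    }
  }
  return Xc;
}

static void col2im_add(const arma::mat& dXc, double* dx, int H, int W, int Cin,
                       int kh, int kw, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (std::size_t)ci * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo + j - pad;
          if (wsrc < 0 || wsrc >= W) continue;
          double* col = xc + (std::size_t)wsrc * H;
          const double* src = dXc.colptr(Ho * wo) + r;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho + i - pad;
            if (hsrc < 0 || hsrc >= H) continue;
            col[hsrc] += src[(std::size_t)ho * dXc.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector bias, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: input channels do not match kernel");
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than padded input");
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  arma::rowvec bv(const_cast<double*>(bias.begin()), Cout, false);
  NumericVector y((std::size_t)Ho * Wo * Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  for (int b = 0; b < B; ++b) {
    arma::mat Xc = im2col(x.begin() + (std::size_t)b * H * W * Cin,
                          H, W, Cin, kh, kw, pad, Ho, Wo);
    arma::mat Y = Xc.t() * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), y.begin() + (std::size_t)b * Ho * Wo * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector dx((std::size_t)H * W * Cin * B);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false);
  arma::rowvec db(Cout, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::mat Xc = im2col(x.begin() + (std::size_t)b * H * W * Cin,
                          H, W, Cin, kh, kw, pad, Ho, Wo);
    arma::mat dYm(const_cast<double*>(dy.begin()) + (std::size_t)b * Ho * Wo * Cout,
                  Ho * Wo, Cout, false);
    dWm += Xc * dYm;
    db += arma::sum(dYm, 0);
    arma::mat dXc = Wm * dYm.t();
    col2im_add(dXc, dx.begin() + (std::size_t)b * H * W * Cin,
               H, W, Cin, kh, kw, pad, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * B);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  std::size_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      std::size_t base = ((std::size_t)b * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          std::size_t p00 = base + (std::size_t)(2 * wo) * H + 2 * ho;
          std::size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
          std::size_t best = cand[0];
          for (int t = 1; t < 4; ++t)
            if (xp[cand[t]] > xp[best]) best = cand[t];
          y[o] = xp[best];
          idx[o] = (int)best;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(IntegerVector idx, NumericVector dy,
                                    IntegerVector xdim) {
  std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[idx[k]] += dy[k];
  return dx;
}

// channel-wise batch normalization (population statistics over H, W, B per
// channel) fused with ReLU; backward consumes the pre-ReLU normalized
// activations and applies the ReLU mask internally
// [[Rcpp::export]]
List cpp_chanbn_forward(NumericVector x, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  std::size_t hw = (std::size_t)H * W;
  NumericVector zn(x.size());
  zn.attr("dim") = xd;
  NumericVector sdv(C);
  std::vector<double> mu(C, 0.0), m2(C, 0.0);
  double n = (double)hw * B;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((std::size_t)b * C + c) * hw;
      double s = 0, s2 = 0;
      for (std::size_t k = 0; k < hw; ++k) { s += p[k]; s2 += p[k] * p[k]; }
      mu[c] += s; m2[c] += s2;
    }
  for (int c = 0; c < C; ++c) {
    mu[c] /= n;
    double v = m2[c] / n - mu[c] * mu[c];
    sdv[c] = std::sqrt((v > 0 ? v : 0) + eps);
  }
  NumericVector act(x.size());
  act.attr("dim") = xd;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((std::size_t)b * C + c) * hw;
      double* q = zn.begin() + ((std::size_t)b * C + c) * hw;
      double* a = act.begin() + ((std::size_t)b * C + c) * hw;
      double m = mu[c], s = sdv[c];
      for (std::size_t k = 0; k < hw; ++k) {
        double z = (p[k] - m) / s;
        q[k] = z;
        a[k] = z > 0 ? z : 0;
      }
    }
  return List::create(_["zn"] = zn, _["sd"] = sdv, _["act"] = act);
}

// [[Rcpp::export]]
NumericVector cpp_chanbn_backward(NumericVector zn, NumericVector sdv,
                                  NumericVector dact) {
  IntegerVector xd = zn.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  std::size_t hw = (std::size_t)H * W;
  double n = (double)hw * B;
  std::vector<double> m1(C, 0.0), m2(C, 0.0);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* da = dact.begin() + ((std::size_t)b * C + c) * hw;
      const double* z = zn.begin() + ((std::size_t)b * C + c) * hw;
      double s1 = 0, s2 = 0;
      for (std::size_t k = 0; k < hw; ++k) {
        double dz = z[k] > 0 ? da[k] : 0;
        s1 += dz; s2 += dz * z[k];
      }
      m1[c] += s1; m2[c] += s2;
    }
  for (int c = 0; c < C; ++c) { m1[c] /= n; m2[c] /= n; }
  NumericVector dx(zn.size());
  dx.attr("dim") = xd;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* da = dact.begin() + ((std::size_t)b * C + c) * hw;
      const double* z = zn.begin() + ((std::size_t)b * C + c) * hw;
      double* out = dx.begin() + ((std::size_t)b * C + c) * hw;
      double a = m1[c], bb = m2[c], s = sdv[c];
      for (std::size_t k = 0; k < hw; ++k) {
        double dz = z[k] > 0 ? da[k] : 0;
        out[k] = (dz - a - z[k] * bb) / s;
      }
    }
  return dx;
}
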