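// Low-level kernels for the detector: im2col+GEMM convolution, max pooling
// and bilinear resize, each with a matching backward pass.  Tensors are R
// arrays in column-major (H, W, C, B) layout; weights are (k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col_one(const double* x, int H, int W, int Cin,
                       int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  // cols: (k*k*Cin) x (Ho*Wo); row r = kh + k*(kw + k*c), col p = ho + Ho*wo
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          double* dst = cols.colptr(0) + r; // advanced manually below
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              cols((size_t)r, (size_t)(ho + Ho * wo)) = 0.0;
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            cols((size_t)r, (size_t)(ho + Ho * wo)) =
              (hi < 0 || hi >= H) ? 0.0 : xc[hi + (size_t)H * wi];
          }
          (void)dst;
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& dcols, int H, int W, int Cin,
                       int k, int stride, int pad, double* dx) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < Cin; ++c) {
    double* dxc = dx + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            dxc[hi + (size_t)H * wi] += dcols((size_t)r, (size_t)(ho + Ho * wo));
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv_forward(NumericVector x, IntegerVector xdim,
                      NumericVector w, IntegerVector wdim,
                      NumericVector bias, int stride, int pad,
                      bool keep_cols) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], B = xdim[3];
  const int k = wdim[0], Cout = wdim[3];
  if (wdim[1] != k || wdim[2] != Cin) stop("weight shape inconsistent with input");
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("output size would be empty");
  const size_t P = (size_t)Ho * Wo;

  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  NumericVector out((R_xlen_t)P * Cout * B);
  arma::mat cols_all;
  if (keep_cols) cols_all.set_size((size_t)k * k * Cin, P * B);
  arma::mat cols((size_t)k * k * Cin, P);

  for (int b = 0; b < B; ++b) {
    im2col_one(x.begin() + (size_t)b * H * W * Cin, H, W, Cin, k, stride, pad, cols);
    arma::mat outm = cols.t() * Wm; // P x Cout
    if (bias.size() == Cout) outm.each_row() += arma::rowvec(const_cast<double*>(bias.begin()), Cout, false, true);
    std::copy(outm.begin(), outm.end(), out.begin() + (size_t)b * P * Cout);
    if (keep_cols) cols_all.cols(P * b, P * (b + 1) - 1) = cols;
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  List res = List::create(_["out"] = out);
  if (keep_cols) res["cols"] = wrap(cols_all);
  return res;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector dout, IntegerVector odim,
                       NumericMatrix cols_all,
                       NumericVector w, IntegerVector wdim,
                       IntegerVector xdim, int stride, int pad,
                       bool need_dx) {
  const int Ho = odim[0], Wo = odim[1], Cout = odim[2], B = odim[3];
  const int H = xdim[0], W = xdim[1], Cin = xdim[2];
  const int k = wdim[0];
  const size_t P = (size_t)Ho * Wo;
  const size_t K2C = (size_t)k * k * Cin;

  const arma::mat Wm(const_cast<double*>(w.begin()), K2C, Cout, false, true);
  const arma::mat cols(const_cast<double*>(cols_all.begin()), K2C, P * B, false, true);

  arma::mat dW(K2C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)H * W * Cin * B);
    dx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  }

  for (int b = 0; b < B; ++b) {
    const arma::mat doutm(const_cast<double*>(dout.begin()) + (size_t)b * P * Cout,
                          P, Cout, false, true);
    const arma::mat colsb = cols.cols(P * b, P * (b + 1) - 1);
    dW += colsb * doutm;
    db += arma::sum(doutm, 0);
    if (need_dx) {
      arma::mat dcols = Wm * doutm.t(); // K2C x P
      col2im_one(dcols, H, W, Cin, k, stride, pad,
                 dx.begin() + (size_t)b * H * W * Cin);
    }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wdim;
  List res = List::create(_["dw"] = dWr,
                          _["db"] = NumericVector(db.begin(), db.end()));
  if (need_dx) res["dx"] = dx;
  return res;
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim,
                         int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const size_t P = (size_t)Ho * Wo;
  NumericVector out((R_xlen_t)P * C * B);
  IntegerVector idx((R_xlen_t)P * C * B); // 0-based linear index into x
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)c + (size_t)C * b) * H * W;
      const size_t base = ((size_t)c + (size_t)C * b) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          const size_t oo = (size_t)(ho + Ho * wo) + P * ((size_t)c + (size_t)C * b);
          out[oo] = best;
          idx[oo] = (int)(base + besti);
          (void)o;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dout, IntegerVector idx,
                                   IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[idx[i]] += dout[i];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, IntegerVector xdim,
                                  int Ho, int Wo) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  NumericVector out((R_xlen_t)Ho * Wo * C);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * H * W;
    double* oc = out.begin() + (size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      double wf = (wo + 0.5) * sw - 0.5;
      int w0 = (int)std::floor(wf);
      double tw = wf - w0;
      int w1 = std::min(std::max(w0 + 1, 0), W - 1);
      w0 = std::min(std::max(w0, 0), W - 1);
      for (int ho = 0; ho < Ho; ++ho) {
        double hf = (ho + 0.5) * sh - 0.5;
        int h0 = (int)std::floor(hf);
        double th = hf - h0;
        int h1 = std::min(std::max(h0 + 1, 0), H - 1);
        h0 = std::min(std::max(h0, 0), H - 1);
        const double v =
          (1 - th) * ((1 - tw) * xc[h0 + (size_t)H * w0] + tw * xc[h0 + (size_t)H * w1]) +
          th       * ((1 - tw) * xc[h1 + (size_t)H * w0] + tw * xc[h1 + (size_t)H * w1]);
        oc[ho + (size_t)Ho * wo] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}
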