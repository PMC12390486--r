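#include <Rcpp.h>
using namespace Rcpp;

// Layout convention for feature tensors throughout the package:
// R arrays with dim (H, W, C, N), column-major, so offset(h,w,c,n) =
// h + H*(w + W*(c + C*n)), all indices 0-based here.

// im2col: rows ordered (kh fastest, then kw, then input channel) so that a
// conv weight array of dim (k, k, Cin, Cout) flattens to the matching
// (k*k*Cin) x Cout matrix. Columns ordered (ho fastest, then wo, then n).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * C, Ho * Wo * N);
  const double* px = x.begin();
  double* po = out.begin();
  int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int col = ho + Ho * (wo + Wo * n);
        double* colp = po + (size_t)col * nrow;
        for (int c = 0; c < C; ++c) {
          const double* xc = px + (size_t)(c + C * n) * H * W;
          for (int kw = 0; kw < k; ++kw) {
            int w = wo * stride - pad + kw;
            for (int kh = 0; kh < k; ++kh) {
              int h = ho * stride - pad + kh;
              double v = 0.0;
              if (h >= 0 && h < H && w >= 0 && w < W) v = xc[h + H * w];
              colp[kh + k * (kw + k * c)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// col2im: adjoint of im2col (accumulates overlapping patches).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  double* po = out.begin();
  const double* pc = cols.begin();
  int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int col = ho + Ho * (wo + Wo * n);
        const double* colp = pc + (size_t)col * nrow;
        for (int c = 0; c < C; ++c) {
          double* xc = po + (size_t)(c + C * n) * H * W;
          for (int kw = 0; kw < k; ++kw) {
            int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              xc[h + H * w] += colp[kh + k * (kw + k * c)];
            }
          }
        }
      }
    }
  }
  return out;
}

// Max pooling with stride and zero-symmetric (-Inf) padding; returns the
// pooled map and 1-based linear argmax indices into the input for backprop.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = px + (size_t)(c + C * n) * H * W;
      size_t base_in = (size_t)(c + C * n) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kw = 0; kw < k; ++kw) {
            int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              double v = xc[h + H * w];
              if (v > best) { best = v; besti = base_in + h + H * w; }
            }
          }
          size_t o = (size_t)(ho + Ho * (wo + Wo * (c + C * n)));
          out[o] = best;
          arg[o] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[argmax[i] - 1] += dout[i];
  return dx;
}
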