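#include <Rcpp.h>
using namespace Rcpp;

// Activation tensors are stored as C x (H*W*N) matrices: one row per
// channel, columns ordered h fastest, then w, then image index n.
// im2col rows are ordered (ki fastest, then kj, then input channel c) so
// a conv weight matrix of shape C_out x (k*k*C) multiplies the patch
// matrix directly.

static inline int col_index(int h, int w, int n, int H, int W) {
  return (n * W + w) * H + h;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& x, int H, int W, int N,
                         int k, int stride, int pad) {
  const int C = x.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(k * k * C, Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int out_col = col_index(ho, wo, n, Ho, Wo);
        int r = 0;
        for (int c = 0; c < C; ++c) {
          for (int kj = 0; kj < k; ++kj) {
            const int w_in = wo * stride - pad + kj;
            for (int ki = 0; ki < k; ++ki, ++r) {
              const int h_in = ho * stride - pad + ki;
              if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W) {
                cols(r, out_col) = x(c, col_index(h_in, w_in, n, H, W));
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& cols, int C, int H, int W,
                         int N, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix dx(C, H * W * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int out_col = col_index(ho, wo, n, Ho, Wo);
        int r = 0;
        for (int c = 0; c < C; ++c) {
          for (int kj = 0; kj < k; ++kj) {
            const int w_in = wo * stride - pad + kj;
            for (int ki = 0; ki < k; ++ki, ++r) {
              const int h_in = ho * stride - pad + ki;
              if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W) {
                dx(c, col_index(h_in, w_in, n, H, W)) += cols(r, out_col);
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling with zero padding (matches a stride-2 3x3 pool after a 1-px
// pad). Returns the pooled map and the flat input column of each argmax so
// the backward pass can scatter gradients.
// [[Rcpp::export]]
List maxpool_fwd_cpp(const NumericMatrix& x, int H, int W, int N,
                     int k, int stride, int pad) {
  const int C = x.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C, Ho * Wo * N);
  IntegerMatrix arg(C, Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int out_col = col_index(ho, wo, n, Ho, Wo);
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          int best_idx = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int w_in = wo * stride - pad + kj;
            if (w_in < 0 || w_in >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h_in = ho * stride - pad + ki;
              if (h_in < 0 || h_in >= H) continue;
              const int idx = col_index(h_in, w_in, n, H, W);
              const double v = x(c, idx);
              if (v > best) { best = v; best_idx = idx; }
            }
          }
          if (best_idx < 0) { best = 0.0; best_idx = 0; }
          out(c, out_col) = best;
          arg(c, out_col) = best_idx;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd_cpp(const NumericMatrix& dout,
                              const IntegerMatrix& arg, int in_cols) {
  const int C = dout.nrow();
  NumericMatrix dx(C, in_cols);
  for (int j = 0; j < dout.ncol(); ++j) {
    for (int c = 0; c < C; ++c) {
      dx(c, arg(c, j)) += dout(c, j);
    }
  }
  return dx;
}

// Average pooling, no padding, floor output size (used for the 2x2
// stride-2 transition pools).
// [[Rcpp::export]]
NumericMatrix avgpool_fwd_cpp(const NumericMatrix& x, int H, int W, int N,
                              int k, int stride) {
  const int C = x.nrow();
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  const double inv = 1.0 / (k * k);
  NumericMatrix out(C, Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int out_col = col_index(ho, wo, n, Ho, Wo);
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            for (int ki = 0; ki < k; ++ki) {
              s += x(c, col_index(ho * stride + ki, wo * stride + kj, n, H, W));
            }
          }
          out(c, out_col) = s * inv;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix avgpool_bwd_cpp(const NumericMatrix& dout, int H, int W,
                              int N, int k, int stride) {
  const int C = dout.nrow();
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  const double inv = 1.0 / (k * k);
  NumericMatrix dx(C, H * W * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int out_col = col_index(ho, wo, n, Ho, Wo);
        for (int c = 0; c < C; ++c) {
          const double g = dout(c, out_col) * inv;
          for (int kj = 0; kj < k; ++kj) {
            for (int ki = 0; ki < k; ++ki) {
              dx(c, col_index(ho * stride + ki, wo * stride + kj, n, H, W)) += g;
            }
          }
        }
      }
    }
  }
  return dx;
}
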