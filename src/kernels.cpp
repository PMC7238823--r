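#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: a batch of feature maps is a column-major R array
// [H, W, C, N] flattened to a vector; linear index i + H*(j + W*(c + C*n)).
// im2col columns are ordered (oy fastest, then ox, then n); rows are
// (ki fastest, then kj, then c). Out-of-image taps read as `fill`.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad_h, int pad_w,
                         int oh, int ow, double fill = 0.0) {
  NumericMatrix out(k * k * C, oh * ow * N);
  double *po = out.begin();
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        R_xlen_t col = (R_xlen_t)oy + (R_xlen_t)oh * (ox + (R_xlen_t)ow * n);
        double *pc = po + col * (R_xlen_t)(k * k * C);
        int i0 = oy * stride - pad_h;
        int j0 = ox * stride - pad_w;
        for (int c = 0; c < C; ++c) {
          R_xlen_t base = (R_xlen_t)H * (W * (c + (R_xlen_t)C * n));
          for (int kj = 0; kj < k; ++kj) {
            int j = j0 + kj;
            for (int ki = 0; ki < k; ++ki) {
              int i = i0 + ki;
              double v = fill;
              if (i >= 0 && i < H && j >= 0 && j < W)
                v = px[base + i + (R_xlen_t)H * j];
              pc[ki + k * (kj + k * c)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch columns back into image space.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad_h, int pad_w,
                         int oh, int ow) {
  NumericVector x((R_xlen_t)H * W * C * N);
  double *px = x.begin();
  const double *po = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        R_xlen_t col = (R_xlen_t)oy + (R_xlen_t)oh * (ox + (R_xlen_t)ow * n);
        const double *pc = po + col * (R_xlen_t)(k * k * C);
        int i0 = oy * stride - pad_h;
        int j0 = ox * stride - pad_w;
        for (int c = 0; c < C; ++c) {
          R_xlen_t base = (R_xlen_t)H * (W * (c + (R_xlen_t)C * n));
          for (int kj = 0; kj < k; ++kj) {
            int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              px[base + i + (R_xlen_t)H * j] += pc[ki + k * (kj + k * c)];
            }
          }
        }
      }
    }
  }
  return x;
}

// Max pooling with "same"-style explicit padding; padded taps count as
// -Inf so the argmax always points inside the image. Returns the pooled
// values and 1-based linear indices into x for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                     int k, int stride, int pad_h, int pad_w,
                     int oh, int ow) {
  R_xlen_t olen = (R_xlen_t)oh * ow * C * N;
  NumericVector out(olen);
  IntegerVector amax(olen);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = (R_xlen_t)H * (W * (c + (R_xlen_t)C * n));
      R_xlen_t obase = (R_xlen_t)oh * (ow * (c + (R_xlen_t)C * n));
      for (int ox = 0; ox < ow; ++ox) {
        for (int oy = 0; oy < oh; ++oy) {
          int i0 = oy * stride - pad_h;
          int j0 = ox * stride - pad_w;
          double best = R_NegInf;
          R_xlen_t bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              R_xlen_t idx = base + i + (R_xlen_t)H * j;
              if (px[idx] > best) { best = px[idx]; bidx = idx; }
            }
          }
          R_xlen_t o = obase + oy + (R_xlen_t)oh * ox;
          out[o] = best;
          amax[o] = (int)(bidx + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector amax,
                              R_xlen_t len) {
  NumericVector dx(len);
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[amax[i] - 1] += dout[i];
  return dx;
}
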