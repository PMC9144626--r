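#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as npix x C matrices; pixel p = r + c*H (0-based,
// column-major, H rows). These kernels only reorganise memory; all matrix
// products run through R's BLAS.

// [[Rcpp::export]]
NumericMatrix cn_im2col3(const NumericMatrix& x, int H, int W) {
  const int C = x.ncol();
  const int n = H * W;
  NumericMatrix out(n, 9 * C);
  for (int ch = 0; ch < C; ++ch) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int q = ch * 9 + (dj + 1) * 3 + (di + 1);
        for (int c = 0; c < W; ++c) {
          const int cc = c + dj;
          if (cc < 0 || cc >= W) continue;
          const int r0 = (di < 0) ? 1 : 0;
          const int r1 = (di > 0) ? H - 1 : H;
          const double* src = &x(0, ch);
          double* dst = &out(0, q);
          for (int r = r0; r < r1; ++r) {
            dst[r + c * H] = src[(r + di) + cc * H];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cn_im2col3: accumulates a gradient w.r.t. the patch matrix
// back onto the input feature map.
// [[Rcpp::export]]
NumericMatrix cn_col2im3(const NumericMatrix& g, int H, int W, int C) {
  const int n = H * W;
  NumericMatrix out(n, C);
  for (int ch = 0; ch < C; ++ch) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int q = ch * 9 + (dj + 1) * 3 + (di + 1);
        for (int c = 0; c < W; ++c) {
          const int cc = c + dj;
          if (cc < 0 || cc >= W) continue;
          const int r0 = (di < 0) ? 1 : 0;
          const int r1 = (di > 0) ? H - 1 : H;
          const double* src = &g(0, q);
          double* dst = &out(0, ch);
          for (int r = r0; r < r1; ++r) {
            dst[(r + di) + cc * H] += src[r + c * H];
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2, returning pooled values and 0-based argmax
// pixel indices (the SegNet pooling indices reused by the decoder).
// [[Rcpp::export]]
List cn_maxpool2(const NumericMatrix& x, int H, int W) {
  const int C = x.ncol();
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix out(Ho * Wo, C);
  IntegerMatrix idx(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = &x(0, ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int p00 = (2 * r) + (2 * c) * H;
        int best = p00;
        double v = src[p00];
        const int cand[3] = { p00 + 1, p00 + H, p00 + H + 1 };
        for (int k = 0; k < 3; ++k) {
          if (src[cand[k]] > v) { v = src[cand[k]]; best = cand[k]; }
        }
        out(r + c * Ho, ch) = v;
        idx(r + c * Ho, ch) = best;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Scatter pooled values (or gradients) back to full resolution at the
// stored indices; serves as unpooling forward and pooling backward.
// [[Rcpp::export]]
NumericMatrix cn_scatter(const NumericMatrix& x, const IntegerMatrix& idx,
                         int H, int W) {
  const int C = x.ncol();
  NumericMatrix out(H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    double* dst = &out(0, ch);
    for (int i = 0; i < x.nrow(); ++i) {
      dst[idx(i, ch)] += x(i, ch);
    }
  }
  return out;
}

// Gather at stored indices: gradient of unpooling.
// [[Rcpp::export]]
NumericMatrix cn_gather(const NumericMatrix& g, const IntegerMatrix& idx) {
  const int C = g.ncol();
  NumericMatrix out(idx.nrow(), C);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = &g(0, ch);
    for (int i = 0; i < idx.nrow(); ++i) {
      out(i, ch) = src[idx(i, ch)];
    }
  }
  return out;
}
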