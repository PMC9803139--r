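#include <Rcpp.h>
using namespace Rcpp;

// Column-major image tensors [H, W, C]. The patch ("lowered") matrix has
// one row per output location (oi + oj*Hout) and one column per kernel
// slot (ki, kj, c) — so the hot inner loops write/read contiguous runs.

static inline void valid_range(int n, int k, int stride, int pad, int dil,
                               int kidx, int nout, int& lo, int& hi) {
  // output positions o with 0 <= o*stride - pad + kidx*dil < n
  int off = kidx * dil - pad;
  lo = off < 0 ? (-off + stride - 1) / stride : 0;
  int hi_excl = (n - off + stride - 1) / stride;  // ceil((n - off)/stride)
  hi = hi_excl < nout ? hi_excl : nout;
  if (lo > hi) lo = hi;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad, int dil) {
  const int Hout = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  const int Wout = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  const int n_out = Hout * Wout;
  NumericMatrix cols(n_out, kh * kw * C);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      int lo_j, hi_j;
      valid_range(W, kw, stride, pad, dil, kj, Wout, lo_j, hi_j);
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kj * kh + c * kh * kw;
        double* dst0 = cp + (size_t)col * n_out;
        int lo_i, hi_i;
        valid_range(H, kh, stride, pad, dil, ki, Hout, lo_i, hi_i);
        for (int oj = lo_j; oj < hi_j; ++oj) {
          const int j = oj * stride - pad + kj * dil;
          const double* src = xp + (size_t)c * H * W + (size_t)j * H
            + (lo_i * stride - pad + ki * dil);
          double* dst = dst0 + (size_t)oj * Hout + lo_i;
          if (stride == 1) {
            std::copy(src, src + (hi_i - lo_i), dst);
          } else {
            for (int oi = lo_i; oi < hi_i; ++oi, ++dst, src += stride)
              *dst = *src;
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add inverse of cpp_im2col.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad, int dil) {
  const int Hout = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  const int Wout = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  const int n_out = Hout * Wout;
  NumericVector out(H * W * C);
  double* op = out.begin();
  const double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      int lo_j, hi_j;
      valid_range(W, kw, stride, pad, dil, kj, Wout, lo_j, hi_j);
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kj * kh + c * kh * kw;
        const double* src0 = cp + (size_t)col * n_out;
        int lo_i, hi_i;
        valid_range(H, kh, stride, pad, dil, ki, Hout, lo_i, hi_i);
        for (int oj = lo_j; oj < hi_j; ++oj) {
          const int j = oj * stride - pad + kj * dil;
          double* dst = op + (size_t)c * H * W + (size_t)j * H
            + (lo_i * stride - pad + ki * dil);
          const double* src = src0 + (size_t)oj * Hout + lo_i;
          if (stride == 1) {
            for (int oi = lo_i; oi < hi_i; ++oi) dst[oi - lo_i] += src[oi - lo_i];
          } else {
            for (int oi = lo_i; oi < hi_i; ++oi, ++src, dst += stride)
              *dst += *src;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// Directed Hausdorff component: max over points a of min over points b of
// the Euclidean distance, on pixel coordinates.
// [[Rcpp::export]]
double cpp_max_min_dist(NumericVector ax, NumericVector ay,
                        NumericVector bx, NumericVector by) {
  const int na = ax.size(), nb = bx.size();
  double worst = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double xi = ax[i], yi = ay[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - bx[j], dy = yi - by[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}
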