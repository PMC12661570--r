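// Low-level image-batch primitives backing the network layers.
// Batch layout everywhere: column-major R array with dim (H, W, C, N).
// im2col rows are ordered (ki fastest, kj, c) to match weight matrices
// built as matrix(w, k*k*Cin, Cout) from a (k, k, Cin, Cout) array.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride) {
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  const int P  = Ho * Wo;
  const int R  = k * k * C;
  NumericMatrix out(R, P * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int planeHW = H * W;
  const int sampleSz = planeHW * C;
  for (int n = 0; n < N; ++n) {
    const double* xs = xp + (size_t)n * sampleSz;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int p = ho + Ho * wo;
        double* col = op + (size_t)(n * P + p) * R;
        const int hi0 = ho * stride;
        const int wi0 = wo * stride;
        int r = 0;
        for (int c = 0; c < C; ++c) {
          const double* plane = xs + (size_t)c * planeHW;
          for (int dj = 0; dj < k; ++dj) {
            const double* colbase = plane + (size_t)(wi0 + dj) * H + hi0;
            for (int di = 0; di < k; ++di) col[r++] = colbase[di];
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col_cpp: cols has dim (k*k*C, P*N) for an
// output image of size (H, W, C, N) sampled with the same (k, stride).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride) {
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  const int P  = Ho * Wo;
  const int R  = k * k * C;
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const int planeHW = H * W;
  const int sampleSz = planeHW * C;
  for (int n = 0; n < N; ++n) {
    double* xs = xp + (size_t)n * sampleSz;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int p = ho + Ho * wo;
        const double* col = cp + (size_t)(n * P + p) * R;
        const int hi0 = ho * stride;
        const int wi0 = wo * stride;
        int r = 0;
        for (int c = 0; c < C; ++c) {
          double* plane = xs + (size_t)c * planeHW;
          for (int dj = 0; dj < k; ++dj) {
            double* colbase = plane + (size_t)(wi0 + dj) * H + hi0;
            for (int di = 0; di < k; ++di) colbase[di] += col[r++];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Non-overlapping max pooling (kernel = stride = p); trailing rows/cols
// that do not fill a bin are dropped, matching floor(H/p) output size.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int N, int p) {
  const int Ho = H / p, Wo = W / p;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based linear index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const int planeHW = H * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * planeHW;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; int bestIdx = -1;
          for (int dj = 0; dj < p; ++dj) {
            const size_t colbase = base + (size_t)(wo * p + dj) * H + ho * p;
            for (int di = 0; di < p; ++di) {
              const double v = xp[colbase + di];
              if (v > best) { best = v; bestIdx = (int)(colbase + di); }
            }
          }
          // column-major output position (ho, wo, c, n)
          const size_t oo = (size_t)ho + (size_t)Ho * wo +
            (size_t)Ho * Wo * c + (size_t)Ho * Wo * C * n;
          yp[oo] = best; ip[oo] = bestIdx;
          ++o;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector gy, IntegerVector idx,
                              int H, int W, int C, int N) {
  NumericVector gx((size_t)H * W * C * N);
  double* gp = gx.begin();
  const double* gyp = gy.begin();
  const int* ip = idx.begin();
  const R_xlen_t M = gy.size();
  for (R_xlen_t i = 0; i < M; ++i) gp[ip[i]] += gyp[i];
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return gx;
}
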