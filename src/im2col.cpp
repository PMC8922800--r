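#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Patch ("im2col") matrix for a stride-1 'same' convolution with zero
// padding. x is an (H, W, N, C) column-major tensor; the result is the
// (H*W*N) x (kh*kh*C) matrix whose row r = h + w*H + n*H*W holds the kh x kh
// neighbourhood of pixel (h, w) in sample n, with columns ordered kernel
// position fastest (k = a + b*kh) then channel, matching the weight layout.
// The columns are contiguous copies of image columns, so the gather is
// effectively a sequence of memcpys.
// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C, int kh) {
  const int p = (kh - 1) / 2;
  const size_t HW = (size_t)H * W;
  const size_t R = HW * N;
  const int K = kh * kh;
  NumericMatrix out((int)R, K * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * HW * N;
    for (int k = 0; k < K; ++k) {
      const int dh = k % kh - p;
      const int dw = k / kh - p;
      double* oc = op + ((size_t)(k + (size_t)c * K)) * R;
      const int h0 = std::max(0, -dh);
      const int h1 = std::min(H, H - dh);
      for (int n = 0; n < N; ++n) {
        const double* xn = xc + (size_t)n * HW;
        double* on = oc + (size_t)n * HW;
        for (int w = 0; w < W; ++w) {
          double* ocol = on + (size_t)w * H;
          const int sw = w + dw;
          if (sw < 0 || sw >= W) {
            std::fill(ocol, ocol + H, 0.0);
            continue;
          }
          const double* xcol = xn + (size_t)sw * H;
          if (h0 > 0) std::fill(ocol, ocol + h0, 0.0);
          std::copy(xcol + h0 + dh, xcol + h1 + dh, ocol + h0);
          if (h1 < H) std::fill(ocol + h1, ocol + H, 0.0);
        }
      }
    }
  }
  return out;
}
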