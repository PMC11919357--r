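#include <Rcpp.h>
using namespace Rcpp;

// Activations are R arrays of dim (H, W, C, N), column-major.
// im2col emits a (k*k*C) x (Ho*Wo*N) matrix; within a column the rows are
// ordered (dy fastest, then dx, then c) so that matrix(W, k*k*C, Cout) built
// from a (k, k, Cin, Cout) kernel array lines up without any permutation.
// Columns are ordered (ho fastest, then wo, then n).

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad, int Ho, int Wo) {
  NumericMatrix out(k * k * C, Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double* colp = op + col * nrow;
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int dx = 0; dx < k; ++dx) {
            const int win = wo * stride - pad + dx;
            for (int dy = 0; dy < k; ++dy) {
              const int hin = ho * stride - pad + dy;
              double v = 0.0;
              if (hin >= 0 && hin < H && win >= 0 && win < W)
                v = xc[hin + (R_xlen_t)H * win];
              colp[dy + k * (dx + k * c)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into an (H, W, C, N) array.
// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad, int Ho, int Wo) {
  NumericVector out((R_xlen_t)H * W * C * N);
  double* op = out.begin();
  const double* cp = cols.begin();
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        const double* colp = cp + col * nrow;
        for (int c = 0; c < C; ++c) {
          double* xc = op + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int dx = 0; dx < k; ++dx) {
            const int win = wo * stride - pad + dx;
            if (win < 0 || win >= W) continue;
            for (int dy = 0; dy < k; ++dy) {
              const int hin = ho * stride - pad + dy;
              if (hin < 0 || hin >= H) continue;
              xc[hin + (R_xlen_t)H * win] += colp[dy + k * (dx + k * c)];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}
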