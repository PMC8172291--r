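// 3x3 same-padding convolution forward/backward via im2col + BLAS GEMM.
// Activation layout matches the R side: column-major (H, W, N, C), i.e.
// flat index h + H*(w + W*(n + N*c)). im2col rows are indexed by (h, w, n)
// and columns by (di, dj, cin), so the GEMM partner is the weight array
// (3, 3, Cin, Cout) flattened to a (9*Cin) x Cout matrix.
// Work is chunked over image columns to bound the im2col buffer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MAX_CHUNK_ELEMS = 3.0e7;  // im2col buffer cap (~240 MB)

static inline int chunkWidth(int H, int W, int N, int Cin) {
  double rowsCap = MAX_CHUNK_ELEMS / (9.0 * Cin);
  int wc = (int)std::floor(rowsCap / ((double)H * N));
  if (wc < 1) wc = 1;
  if (wc > W) wc = W;
  return wc;
}

// Fill the im2col block for image columns [w0, w1); rows ordered
// h + H*((w - w0) + (w1 - w0)*n).
static void im2col(const double* x, arma::mat& cols, int H, int W, int N,
                   int Cin, int w0, int w1) {
  const int wBlk = w1 - w0;
  cols.zeros();
  for (int c = 0; c < Cin; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = (di + 1) + 3 * ((dj + 1) + 3 * c);
        double* dst = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          for (int w = w0; w < w1; ++w) {
            const int ws = w + dj;
            if (ws < 0 || ws >= W) continue;
            const double* src =
                x + (size_t)H * (ws + (size_t)W * (n + (size_t)N * c));
            double* d = dst + (size_t)H * ((w - w0) + (size_t)wBlk * n);
            const int h0 = (di < 0) ? 1 : 0;
            const int h1 = (di > 0) ? H - 1 : H;
            for (int h = h0; h < h1; ++h) d[h] = src[h + di];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3x3Fwd")]]
NumericVector conv3x3Fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3], Cout = dw[3];
  const arma::mat Wmat(const_cast<double*>(w.begin()), 9 * Cin, Cout, false);
  NumericVector y((size_t)H * W * N * Cout);
  const int wc = chunkWidth(H, W, N, Cin);
  for (int w0 = 0; w0 < W; w0 += wc) {
    const int w1 = std::min(W, w0 + wc);
    const int wBlk = w1 - w0;
    arma::mat cols((size_t)H * wBlk * N, 9 * Cin);
    im2col(x.begin(), cols, H, W, N, Cin, w0, w1);
    arma::mat out = cols * Wmat;
    out.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false);
    // scatter rows back: (h, w-w0, n, c) -> (h, w, n, c)
    for (int c = 0; c < Cout; ++c) {
      const double* src = out.colptr(c);
      for (int n = 0; n < N; ++n) {
        for (int ww = w0; ww < w1; ++ww) {
          double* d = y.begin() +
              (size_t)H * (ww + (size_t)W * (n + (size_t)N * c));
          const double* s = src + (size_t)H * ((ww - w0) + (size_t)wBlk * n);
          std::copy(s, s + H, d);
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, N, Cout);
  return y;
}

// [[Rcpp::export(name = ".conv3x3Bwd")]]
List conv3x3Bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3], Cout = dw[3];
  const arma::mat Wmat(const_cast<double*>(w.begin()), 9 * Cin, Cout, false);
  NumericVector dxOut((size_t)H * W * N * Cin);
  NumericVector dwOut(9 * Cin * Cout);
  arma::mat dWmat(dwOut.begin(), 9 * Cin, Cout, false, true);
  NumericVector db(Cout);
  const int wc = chunkWidth(H, W, N, Cin);
  for (int w0 = 0; w0 < W; w0 += wc) {
    const int w1 = std::min(W, w0 + wc);
    const int wBlk = w1 - w0;
    arma::mat cols((size_t)H * wBlk * N, 9 * Cin);
    im2col(x.begin(), cols, H, W, N, Cin, w0, w1);
    // gather dy rows for this chunk
    arma::mat dyBlk((size_t)H * wBlk * N, Cout);
    for (int c = 0; c < Cout; ++c) {
      double* d = dyBlk.colptr(c);
      for (int n = 0; n < N; ++n) {
        for (int ww = w0; ww < w1; ++ww) {
          const double* s = dy.begin() +
              (size_t)H * (ww + (size_t)W * (n + (size_t)N * c));
          std::copy(s, s + H, d + (size_t)H * ((ww - w0) + (size_t)wBlk * n));
        }
      }
    }
    dWmat += cols.t() * dyBlk;
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dyBlk.col(c));
    arma::mat dcols = dyBlk * Wmat.t();
    // col2im scatter-add
    for (int c = 0; c < Cin; ++c) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int col = (di + 1) + 3 * ((dj + 1) + 3 * c);
          const double* src = dcols.colptr(col);
          for (int n = 0; n < N; ++n) {
            for (int ww = w0; ww < w1; ++ww) {
              const int ws = ww + dj;
              if (ws < 0 || ws >= W) continue;
              double* d = dxOut.begin() +
                  (size_t)H * (ws + (size_t)W * (n + (size_t)N * c));
              const double* s =
                  src + (size_t)H * ((ww - w0) + (size_t)wBlk * n);
              const int h0 = (di < 0) ? 1 : 0;
              const int h1 = (di > 0) ? H - 1 : H;
              for (int h = h0; h < h1; ++h) d[h + di] += s[h];
            }
          }
        }
      }
    }
  }
  dxOut.attr("dim") = IntegerVector::create(H, W, N, Cin);
  dwOut.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  return List::create(Named("dx") = dxOut, Named("dW") = dwOut,
                      Named("db") = db);
}
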