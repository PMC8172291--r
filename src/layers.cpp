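// Fused batch-norm + leaky-ReLU and 2x2 max-pool kernels. Layout (H, W, N, C)
// column-major: each channel is one contiguous slice of M = H*W*N values.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bnLreluFwd")]]
List bnLreluFwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector runMean, NumericVector runVar, bool training,
                double eps, double momentum, double slope) {
  IntegerVector d = x.attr("dim");
  const size_t M = (size_t)d[0] * d[1] * d[2];
  const int C = d[3];
  NumericVector y(x.size());
  NumericVector mu(C), invstd(C);
  NumericVector rm = clone(runMean), rv = clone(runVar);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + M * c;
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (size_t i = 0; i < M; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      rm[c] = (1 - momentum) * rm[c] + momentum * m;
      rv[c] = (1 - momentum) * rv[c] + momentum * v;
    } else {
      m = runMean[c];
      v = runVar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m; invstd[c] = is;
    const double a = gamma[c] * is;
    const double b = beta[c] - a * m;
    double* yc = y.begin() + M * c;
    for (size_t i = 0; i < M; ++i) {
      const double z = a * xc[i] + b;
      yc[i] = z > 0 ? z : slope * z;
    }
  }
  y.attr("dim") = d;
  return List::create(Named("y") = y, Named("mu") = mu,
                      Named("invstd") = invstd, Named("runMean") = rm,
                      Named("runVar") = rv);
}

// [[Rcpp::export(name = ".bnLreluBwd")]]
List bnLreluBwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mu, NumericVector invstd, NumericVector dy,
                double slope, bool training) {
  IntegerVector d = x.attr("dim");
  const size_t M = (size_t)d[0] * d[1] * d[2];
  const int C = d[3];
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  std::vector<double> dbn(M);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + M * c;
    const double* dyc = dy.begin() + M * c;
    double* dxc = dx.begin() + M * c;
    const double a = gamma[c] * invstd[c];
    const double b = beta[c] - a * mu[c];
    double sdb = 0, sdg = 0;
    for (size_t i = 0; i < M; ++i) {
      const double z = a * xc[i] + b;
      const double g = (z > 0 ? dyc[i] : slope * dyc[i]);
      dbn[i] = g;
      sdb += g;
      sdg += g * (xc[i] - mu[c]) * invstd[c];
    }
    dgamma[c] = sdg;
    dbeta[c] = sdb;
    if (training) {
      const double mdb = sdb / M, mdg = sdg / M;
      for (size_t i = 0; i < M; ++i) {
        const double xhat = (xc[i] - mu[c]) * invstd[c];
        dxc[i] = a * (dbn[i] - mdb - xhat * mdg);
      }
    } else {
      for (size_t i = 0; i < M; ++i) dxc[i] = a * dbn[i];
    }
  }
  dx.attr("dim") = d;
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = ".pool2Fwd")]]
List pool2Fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * N * C);
  IntegerVector idx(y.size());
  size_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w) {
        const size_t base = (size_t)H * (2 * w + (size_t)W * (n + (size_t)N * c));
        for (int h = 0; h < Ho; ++h, ++o) {
          const size_t i00 = base + 2 * h;
          const double v[4] = {x[i00], x[i00 + H], x[i00 + 1], x[i00 + H + 1]};
          int best = 0;
          for (int k = 1; k < 4; ++k) if (v[k] > v[best]) best = k;
          y[o] = v[best];
          idx[o] = best;
        }
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export(name = ".pool2Bwd")]]
NumericVector pool2Bwd(NumericVector dy, IntegerVector idx, IntegerVector dimx) {
  const int H = dimx[0], W = dimx[1], N = dimx[2], C = dimx[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)H * W * N * C);
  size_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w) {
        const size_t base = (size_t)H * (2 * w + (size_t)W * (n + (size_t)N * c));
        for (int h = 0; h < Ho; ++h, ++o) {
          const size_t i00 = base + 2 * h;
          const int k = idx[o];
          const size_t tgt = i00 + (k == 1 || k == 3 ? H : 0) +
                             (k == 2 || k == 3 ? 1 : 0);
          dx[tgt] += dy[o];
        }
      }
  dx.attr("dim") = dimx;
  return dx;
}
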