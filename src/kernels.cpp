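// Hot inner loops of the network: depthwise-convolution taps, exact GELU,
// batch-normalization statistics, and fused row-vector adds. Everything here
// is a straight translation of the vectorized R formulation; shapes are
// column-major R arrays (batch fastest).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double INV_SQRT2 = 0.7071067811865475;
static const double INV_SQRT_2PI = 0.3989422804014327;

// depthwise k x k tap accumulation over a zero-padded input.
// xp: (N, Hp, Wp, C) with Hp = H + k - 1; W_taps: (k*k, C) taps enumerated
// row-major over (dy, dx); bias: length C (ignored unless add_bias).
// Returns y: (N, H, W, C).
// [[Rcpp::export]]
NumericVector dw_taps_cpp(const NumericVector& xp, const IntegerVector& dims_p,
                          int k, int H, int W, const NumericMatrix& W_taps,
                          const NumericVector& bias, bool add_bias) {
  const int N = dims_p[0], Hp = dims_p[1], Wp = dims_p[2], C = dims_p[3];
  NumericVector y(static_cast<R_xlen_t>(N) * H * W * C);
  const double* px = xp.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    if (add_bias) {
      const double b = bias[c];
      double* dst0 = py + static_cast<R_xlen_t>(N) * H * W * c;
      for (R_xlen_t t = 0; t < static_cast<R_xlen_t>(N) * H * W; ++t) dst0[t] = b;
    }
    for (int tap = 0; tap < k * k; ++tap) {
      const double w = W_taps(tap, c);
      if (w == 0.0) continue;
      const int dy = tap / k, dx = tap % k;
      for (int j = 0; j < W; ++j) {
        const double* src = px + static_cast<R_xlen_t>(N) *
          (dy + static_cast<R_xlen_t>(Hp) * ((j + dx) + static_cast<R_xlen_t>(Wp) * c));
        double* dst = py + static_cast<R_xlen_t>(N) *
          (static_cast<R_xlen_t>(H) * (j + static_cast<R_xlen_t>(W) * c));
        for (int i = 0; i < H; ++i) {
          const double* s = src + static_cast<R_xlen_t>(N) * i;
          double* d = dst + static_cast<R_xlen_t>(N) * i;
          for (int n = 0; n < N; ++n) d[n] += w * s[n];
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(N, H, W, C);
  return y;
}

// tap-weight gradient: gw(tap, c) = sum_{n,i,j} xp[n, i+dy, j+dx, c] * g[n, i, j, c]
// [[Rcpp::export]]
NumericMatrix dw_gradw_cpp(const NumericVector& xp, const IntegerVector& dims_p,
                           int k, const NumericVector& g, int H, int W) {
  const int N = dims_p[0], Hp = dims_p[1], Wp = dims_p[2], C = dims_p[3];
  NumericMatrix gw(k * k, C);
  const double* px = xp.begin();
  const double* pg = g.begin();
  for (int c = 0; c < C; ++c) {
    for (int tap = 0; tap < k * k; ++tap) {
      const int dy = tap / k, dx = tap % k;
      double acc = 0.0;
      for (int j = 0; j < W; ++j) {
        const double* src = px + static_cast<R_xlen_t>(N) *
          (dy + static_cast<R_xlen_t>(Hp) * ((j + dx) + static_cast<R_xlen_t>(Wp) * c));
        const double* gr = pg + static_cast<R_xlen_t>(N) *
          (static_cast<R_xlen_t>(H) * (j + static_cast<R_xlen_t>(W) * c));
        for (int i = 0; i < H; ++i) {
          const double* s = src + static_cast<R_xlen_t>(N) * i;
          const double* d = gr + static_cast<R_xlen_t>(N) * i;
          for (int n = 0; n < N; ++n) acc += s[n] * d[n];
        }
      }
      gw(tap, c) = acc;
    }
  }
  return gw;
}

// exact GELU: returns list(y = x * Phi(x), ph = Phi(x))
// [[Rcpp::export]]
List gelu_fwd_cpp(const NumericVector& x) {
  R_xlen_t n = x.size();
  NumericVector y(n), ph(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double p = 0.5 * (1.0 + std::erf(x[i] * INV_SQRT2));
    ph[i] = p;
    y[i] = x[i] * p;
  }
  if (!Rf_isNull(x.attr("dim"))) {
    y.attr("dim") = x.attr("dim");
    ph.attr("dim") = x.attr("dim");
  }
  return List::create(Named("y") = y, Named("ph") = ph);
}

// GELU derivative given cached Phi(x): Phi(x) + x * phi(x)
// [[Rcpp::export]]
NumericVector gelu_grad_cpp(const NumericVector& x, const NumericVector& ph) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = ph[i] + x[i] * std::exp(-0.5 * x[i] * x[i]) * INV_SQRT_2PI;
  if (!Rf_isNull(x.attr("dim"))) out.attr("dim") = x.attr("dim");
  return out;
}

// m + row vector v (recycled down columns)
// [[Rcpp::export]]
NumericMatrix add_rowvec_cpp(const NumericMatrix& m, const NumericVector& v) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double vj = v[j];
    const double* src = &m(0, j);
    double* dst = &out(0, j);
    for (int i = 0; i < nr; ++i) dst[i] = src[i] + vj;
  }
  return out;
}

// batch-norm training forward on (m x C): returns y, xhat, mu, var
// [[Rcpp::export]]
List bn_fwd_cpp(const NumericMatrix& x, const NumericVector& gamma,
                const NumericVector& beta, double eps) {
  const int m = x.nrow(), C = x.ncol();
  NumericMatrix y(m, C), xhat(m, C);
  NumericVector mu(C), var(C), inv(C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += px[i];
    const double mc = s / m;
    double v = 0.0;
    for (int i = 0; i < m; ++i) {
      const double d = px[i] - mc;
      v += d * d;
    }
    v /= m;
    const double ic = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    double* ph = &xhat(0, c);
    double* py = &y(0, c);
    for (int i = 0; i < m; ++i) {
      const double h = (px[i] - mc) * ic;
      ph[i] = h;
      py[i] = g * h + b;
    }
    mu[c] = mc; var[c] = v; inv[c] = ic;
  }
  return List::create(Named("y") = y, Named("xhat") = xhat, Named("mu") = mu,
                      Named("var") = var, Named("inv") = inv);
}

// batch-norm backward: returns dx plus the dgamma/dbeta contributions
// [[Rcpp::export]]
List bn_bwd_cpp(const NumericMatrix& g, const NumericMatrix& xhat,
                const NumericVector& inv, const NumericVector& gamma) {
  const int m = g.nrow(), C = g.ncol();
  NumericMatrix dx(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* pg = &g(0, c);
    const double* ph = &xhat(0, c);
    double sg = 0.0, sgh = 0.0;
    for (int i = 0; i < m; ++i) {
      sg += pg[i];
      sgh += pg[i] * ph[i];
    }
    dgamma[c] = sgh;
    dbeta[c] = sg;
    const double gam = gamma[c], ic = inv[c];
    const double c1 = gam * sg / m, c2 = gam * sgh / m;
    double* pd = &dx(0, c);
    for (int i = 0; i < m; ++i)
      pd[i] = ic * (gam * pg[i] - c1 - ph[i] * c2);
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
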