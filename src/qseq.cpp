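#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sliding-window empirical-likelihood statistic sequence.
//
// Maintains the window's running sum s and uncentred cross-product matrix C
// (lower triangle) under rank-two slide updates; C is rebuilt from scratch
// every 1024 windows to stop floating-point drift from accumulating over long
// in-control runs.  Per window this forms the sample covariance implicitly
// and evaluates tr(S), tr(S^2), gamma'S gamma, gamma'S^2 gamma, the anchor
// scale, the closed-form log-ratio and the standardized statistic Q.
//
// [[Rcpp::export]]
NumericVector q_seq_cpp(const NumericMatrix& X, int D, const NumericVector& mu0,
                        double ln, double kn, const NumericVector& gamma,
                        bool bias_corrected) {
  const int T = X.nrow(), p = X.ncol();
  if (mu0.size() != p || gamma.size() != p)
    stop("dimension mismatch between stream, mu0 and gamma");
  if (T < D) stop("stream shorter than window size D");
  if (D < 2) stop("window size must be at least 2");
  if (bias_corrected && D < 4) stop("bias-corrected mode needs D >= 4");
  const int m = T - D + 1;
  const double n = static_cast<double>(D);
  NumericVector out(m);
  std::vector<double> s(p), C(static_cast<size_t>(p) * p), Sg(p);

  auto rebuild = [&](int start) {
    std::fill(s.begin(), s.end(), 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    for (int i = start; i < start + D; ++i)
      for (int a = 0; a < p; ++a) {
        const double xa = X(i, a);
        s[a] += xa;
        for (int b = 0; b <= a; ++b)
          C[static_cast<size_t>(a) * p + b] += xa * X(i, b);
      }
  };
  rebuild(0);

  const double fac = 2.0 * n * ln * ln / ((n + 2.0) * (n + 2.0));
  const double bc = (n - 1.0) * (n - 1.0) / ((n - 2.0) * (n + 1.0));

  for (int k = 0; k < m; ++k) {
    if (k > 0) {
      if (k % 1024 == 0) {
        rebuild(k);
      } else {
        const int oi = k - 1, ii = k + D - 1;
        for (int a = 0; a < p; ++a) {
          const double xo = X(oi, a), xi = X(ii, a);
          s[a] += xi - xo;
          for (int b = 0; b <= a; ++b)
            C[static_cast<size_t>(a) * p + b] += xi * X(ii, b) - xo * X(oi, b);
        }
      }
    }

    double dn2 = 0.0, gd = 0.0, trS = 0.0, trS2_off = 0.0, trS2 = 0.0,
      gSg = 0.0, gS2g = 0.0;
    const double inv = 1.0 / (n - 1.0);
    std::fill(Sg.begin(), Sg.end(), 0.0);
    for (int a = 0; a < p; ++a) {
      const double xb_a = s[a] / n;
      const double d_a = xb_a - mu0[a];
      dn2 += d_a * d_a;
      gd += gamma[a] * d_a;
      const double ga = gamma[a];
      const double* Ca = &C[static_cast<size_t>(a) * p];
      double sg_a = 0.0;
      for (int b = 0; b < a; ++b) {
        const double v = (Ca[b] - xb_a * s[b]) * inv;
        trS2_off += v * v;
        sg_a += v * gamma[b];
        Sg[b] += v * ga;
      }
      const double vd = (Ca[a] - xb_a * s[a]) * inv;
      trS += vd;
      trS2 += vd * vd;
      Sg[a] += sg_a + vd * ga;
    }
    trS2 += 2.0 * trS2_off;
    for (int a = 0; a < p; ++a) {
      gSg += gamma[a] * Sg[a];
      gS2g += Sg[a] * Sg[a];
    }
    if (trS2 <= 0.0)
      stop("degenerate window (zero dispersion) at position %d", k + 1);

    const double trSig2 =
      bias_corrected ? bc * (trS2 - trS * trS / (n - 1.0)) : trS2;
    const double trOm = trS + kn * gSg;
    const double trOm2 = trSig2 + 2.0 * kn * gS2g + kn * kn * gSg * gSg;
    if (trOm2 <= 0.0)
      stop("nonpositive tr(Omega^2) estimate at position %d", k + 1);

    double W = 0.0;
    const double den2 = dn2 + kn * gd * gd;
    if (den2 > 0.0) {
      const double an = ln / std::sqrt(den2);
      const double xi = (n + 2.0) / (1.0 + an);
      const double r = std::sqrt(1.0 + n / (n + 2.0) * xi * xi);
      double t1 = 1.0 + (1.0 - r) / n;
      if (t1 < 1e-300) t1 = 1e-300;
      const double t2 = 0.5 + 0.5 * xi + 0.5 * r;
      double t3 = 0.5 - 0.5 * xi + 0.5 * r;
      if (t3 < 1e-300) t3 = 1e-300;
      W = -2.0 * (n * std::log(t1) + std::log(t2) + std::log(t3));
      if (W < 0.0) W = 0.0;
    }
    out[k] = (fac * W - trOm) / std::sqrt(2.0 * trOm2);
  }
  return out;
}
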