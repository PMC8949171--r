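#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalized (Pearson) cross-correlation of a template against every
// length-m window of a search signal. Returns one value per integer lag
// 0..(L - m). Windows with (near) zero variance yield r = 0: they carry no
// shape information and must not win the peak search.
// [[Rcpp::export(name = ".ncc_kernel")]]
NumericVector ncc_kernel(NumericVector templ, NumericVector search) {
  const int m = templ.size();
  const int L = search.size();
  if (L < m) stop("search shorter than template");
  const int nlag = L - m + 1;

  double tmean = 0.0;
  for (int i = 0; i < m; ++i) tmean += templ[i];
  tmean /= m;
  std::vector<double> tc(m);
  double tss = 0.0;
  for (int i = 0; i < m; ++i) {
    tc[i] = templ[i] - tmean;
    tss += tc[i] * tc[i];
  }
  if (tss <= 0.0) stop("zero-variance template: correlation undefined");
  const double tnorm = std::sqrt(tss);

  // running window sums for mean/variance of each search window
  double s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < m; ++i) { s1 += search[i]; s2 += search[i] * search[i]; }

  NumericVector r(nlag);
  const double eps = 1e-30;
  for (int k = 0; k < nlag; ++k) {
    double num = 0.0;
    for (int i = 0; i < m; ++i) num += search[k + i] * tc[i];
    double wss = s2 - s1 * s1 / m;
    if (wss < eps) {
      r[k] = 0.0;
    } else {
      double val = num / (tnorm * std::sqrt(wss));
      if (val > 1.0) val = 1.0; else if (val < -1.0) val = -1.0;
      r[k] = val;
    }
    if (k + m < L) {
      const double out = search[k], in = search[k + m];
      s1 += in - out;
      s2 += in * in - out * out;
    }
  }
  return r;
}

// Order-(na-1) IIR filter, direct form II transposed; one forward pass.
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 std::vector<double>& x) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j) {
      z[j] = z[j + 1] + (j + 1 < nb ? b[j + 1] * xi : 0.0)
                      - (j + 1 < na ? a[j + 1] * yi : 0.0);
    }
    z[nz - 1] = (nz < nb ? b[nz] * xi : 0.0) - (nz < na ? a[nz] * yi : 0.0);
    x[i] = yi;
  }
}

// Zero-phase filtering: forward pass, reverse, second pass, reverse.
// No edge padding; callers rescale the output to a target SD afterwards,
// which absorbs the startup transient's amplitude loss.
// [[Rcpp::export(name = ".filtfilt_kernel")]]
NumericVector filtfilt_kernel(NumericVector b, NumericVector a, NumericVector x) {
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  if (aa.empty() || aa[0] == 0.0) stop("a[1] must be nonzero");
  if (aa[0] != 1.0) {
    for (auto& v : bb) v /= aa[0];
    for (auto& v : aa) v /= aa[0];
  }
  std::vector<double> y(x.begin(), x.end());
  df2t(bb, aa, y);
  std::reverse(y.begin(), y.end());
  df2t(bb, aa, y);
  std::reverse(y.begin(), y.end());
  return NumericVector(y.begin(), y.end());
}

// Underdamped second-order impulse response evaluated at times t (seconds,
// relative to excitation onset): gain * exp(-zeta*wn*t) * sin(wd*t), zero for
// t < 0. Shared by the simulator's per-channel delayed evaluation.
// [[Rcpp::export(name = ".sdof_impulse_kernel")]]
NumericVector sdof_impulse_kernel(NumericVector t, double wn, double zeta,
                                  double gain) {
  const int n = t.size();
  const double wd = wn * std::sqrt(1.0 - zeta * zeta);
  const double sig = zeta * wn;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ti = t[i];
    out[i] = (ti <= 0.0) ? 0.0 : gain * std::exp(-sig * ti) * std::sin(wd * ti);
  }
  return out;
}
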