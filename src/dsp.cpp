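// Streaming DSP primitives: stateful IIR filtering and Burg autoregressive
// band-power estimation. Kept in C++ because the feature pipeline runs them
// once per channel per 33.3 ms frame.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct-form II transposed IIR filter with carried state.
// b, a: coefficients with a[0] == 1 (caller normalizes). zi: state of
// length max(nb, na) - 1 (pass zeros for a cold start). Returns the
// filtered block and the final state so frame-by-frame calls are
// bit-identical to one long call.
// [[Rcpp::export(name = ".iir_filter")]]
List iir_filter(NumericVector b, NumericVector a, NumericVector x,
                NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  if ((int)zi.size() != nz) stop("state length must be %d", nz);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (aa[0] != 1.0) {
    if (aa[0] == 0.0) stop("a[0] must be nonzero");
    for (int i = 0; i <= nz; ++i) { bb[i] /= aa[0] == 0 ? 1 : a[0]; }
    for (int i = 0; i <= nz; ++i) { aa[i] /= a[0]; }
  }
  int n = x.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    if (nz > 0) z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return List::create(_["y"] = y, _["zf"] = NumericVector(z.begin(), z.end()));
}

// Burg recursion on a (not demeaned) series. Returns AR coefficients a_k in
// the convention x_t = sum_k a_k x_{t-k} + e_t and the driving-noise
// variance estimate.
static void burg_fit(const double *x, int n, int order,
                     std::vector<double> &a, double &vpred) {
  std::vector<double> f(x, x + n), b(x, x + n), aprev(order, 0.0);
  a.assign(order, 0.0);
  double e = 0.0;
  for (int t = 0; t < n; ++t) e += x[t] * x[t];
  e /= n;
  // denominator by Andersen's recursion instead of a per-order rescan
  double den = 0.0;
  for (int t = 1; t < n; ++t) den += f[t] * f[t] + b[t - 1] * b[t - 1];
  double *fp = f.data(), *bp = b.data();
  for (int m = 1; m <= order; ++m) {
    double num = 0.0;
    for (int t = m; t < n; ++t) num += fp[t] * bp[t - 1];
    double k = den > 0 ? 2.0 * num / den : 0.0;
    aprev = a;
    a[m - 1] = k;
    for (int j = 1; j < m; ++j) a[j - 1] = aprev[j - 1] - k * aprev[m - j - 1];
    for (int t = n - 1; t >= m; --t) {
      double ft = fp[t], bt = bp[t - 1];
      fp[t] = ft - k * bt;
      bp[t] = bt - k * ft;
    }
    e *= (1.0 - k * k);
    if (m < order)
      den = (1.0 - k * k) * den - fp[m] * fp[m] - bp[n - 1] * bp[n - 1];
  }
  vpred = e;
}

// [[Rcpp::export(name = ".burg_fit")]]
List burg_fit_r(NumericVector x, int order) {
  if ((int)x.size() < 2 * order) stop("series too short for AR order");
  std::vector<double> a;
  double v;
  burg_fit(x.begin(), x.size(), order, a, v);
  return List::create(_["ar"] = NumericVector(a.begin(), a.end()),
                      _["var_pred"] = v);
}

// One-sided AR power spectral density integrated over frequency bins.
// X: channels x samples (rows are channels, already windowed).
// band_edges: Hz, strictly increasing, length n_bands + 1.
// grid_per_bin: trapezoid sub-intervals per bin.
// Rows are demeaned before fitting. Returns channels x n_bands.
// [[Rcpp::export(name = ".burg_band_power")]]
NumericMatrix burg_band_power(NumericMatrix X, int order, double fs,
                              NumericVector band_edges, int grid_per_bin) {
  int nch = X.nrow(), n = X.ncol();
  int nbands = band_edges.size() - 1;
  if (nbands < 1) stop("need at least one band");
  if (n < 2 * order) stop("window too short for AR order");
  NumericMatrix out(nch, nbands);
  // frequency grid, shared across channels
  std::vector<double> freqs;
  std::vector<int> bin_of;
  for (int bnd = 0; bnd < nbands; ++bnd) {
    double lo = band_edges[bnd], hi = band_edges[bnd + 1];
    for (int g = 0; g <= grid_per_bin; ++g) {
      freqs.push_back(lo + (hi - lo) * g / grid_per_bin);
      bin_of.push_back(bnd);
    }
  }
  int nf = freqs.size();
  std::vector<double> xw(n), a, psd(nf);
  for (int c = 0; c < nch; ++c) {
    double mu = 0.0;
    for (int t = 0; t < n; ++t) mu += X(c, t);
    mu /= n;
    bool constant = true;
    for (int t = 0; t < n; ++t) {
      xw[t] = X(c, t) - mu;
      if (constant && std::abs(xw[t]) > 1e-12 * (std::abs(mu) + 1.0))
        constant = false;
    }
    if (constant) stop("degenerate (constant) signal in channel %d", c + 1);
    double v;
    burg_fit(xw.data(), n, order, a, v);
    for (int i = 0; i < nf; ++i) {
      double w = 2.0 * M_PI * freqs[i] / fs;
      // A(e^{-iw}) = 1 - sum_k a_k e^{-iwk}, accumulated by rotation
      double cw = std::cos(w), sw = std::sin(w);
      double ck = 1.0, sk = 0.0; // e^{-i w 0}
      double re = 1.0, im = 0.0;
      for (int k = 0; k < order; ++k) {
        double ck1 = ck * cw + sk * sw; // cos((k+1)w)
        double sk1 = sk * cw - ck * sw; // -sin((k+1)w) accumulated as e^{-iw(k+1)}
        ck = ck1; sk = sk1;
        re -= a[k] * ck;
        im -= a[k] * sk;
      }
      double denom = re * re + im * im;
      psd[i] = 2.0 * v / (fs * (denom > 1e-300 ? denom : 1e-300));
    }
    // trapezoid per bin
    for (int bnd = 0; bnd < nbands; ++bnd) {
      double lo = band_edges[bnd], hi = band_edges[bnd + 1];
      double h = (hi - lo) / grid_per_bin;
      int base = bnd * (grid_per_bin + 1);
      double s = 0.5 * (psd[base] + psd[base + grid_per_bin]);
      for (int g = 1; g < grid_per_bin; ++g) s += psd[base + g];
      out(c, bnd) = s * h;
    }
  }
  return out;
}

// One full simulator frame for all channels in a single call.
// white: channels x samples standard-normal draws (from R's RNG streams).
// pink sections: nsec x 2 matrices of (b0, b1) and (1, a1) coefficients.
// States are modified in place: pink_z (channels x nsec), fir_z
// (channels x (ntaps-1), the trailing input history), delay_buf
// (channels x D). gains: per-channel modulation gain d*cos(theta - PD)
// (pass 0 when the drive is inactive). scale: output amplitude.
// Returns channels x samples output S = S1_delayed + gain * S2.
// [[Rcpp::export(name = ".sim_frame")]]
NumericMatrix sim_frame(NumericMatrix white, NumericMatrix pink_b,
                        NumericMatrix pink_a, NumericMatrix pink_z,
                        double pink_gain, NumericVector fir,
                        NumericMatrix fir_z, NumericMatrix delay_buf,
                        NumericVector gains, double scale) {
  int nch = white.nrow(), ns = white.ncol();
  int nsec = pink_b.nrow();
  int ntaps = fir.size(), nh = ntaps - 1;
  int D = delay_buf.ncol();
  NumericMatrix out(nch, ns);
  std::vector<double> p(ns), joined(nh + ns), dj(D + ns);
  const double *h = fir.begin();
  for (int c = 0; c < nch; ++c) {
    // pink cascade (first-order sections, direct form II transposed)
    for (int t = 0; t < ns; ++t) p[t] = white(c, t);
    for (int s = 0; s < nsec; ++s) {
      double b0 = pink_b(s, 0), b1 = pink_b(s, 1), a1 = pink_a(s, 1);
      double z = pink_z(c, s);
      for (int t = 0; t < ns; ++t) {
        double y = b0 * p[t] + z;
        z = b1 * p[t] - a1 * y;
        p[t] = y;
      }
      pink_z(c, s) = z;
    }
    double amp = scale / pink_gain;
    for (int t = 0; t < ns; ++t) p[t] *= amp;
    // FIR band-pass over [history | block]
    for (int k = 0; k < nh; ++k) joined[k] = fir_z(c, k);
    for (int t = 0; t < ns; ++t) joined[nh + t] = p[t];
    double g = gains[c];
    // delayed S1
    for (int k = 0; k < D; ++k) dj[k] = delay_buf(c, k);
    for (int t = 0; t < ns; ++t) dj[D + t] = p[t];
    for (int t = 0; t < ns; ++t) {
      double acc = 0.0;
      const double *jp = &joined[nh + t];
      for (int k = 0; k < ntaps; ++k) acc += h[k] * jp[-k];
      out(c, t) = dj[t] + g * acc;
    }
    for (int k = 0; k < nh; ++k) fir_z(c, k) = joined[ns + k];
    for (int k = 0; k < D; ++k) delay_buf(c, k) = dj[ns + k];
  }
  return out;
}
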