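#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Forward Beer-Lambert: intensity per wavelength from concentration series.
// hbo/hbr are [time x channel] (molar); e* are natural-log extinction
// coefficients; path = separation * ppf per channel. White measurement
// noise of SD `noise_sd` (R's RNG) is added in the same pass when > 0.
// [[Rcpp::export]]
List forward_intensity(NumericMatrix hbo, NumericMatrix hbr,
                       NumericVector path, double e1o, double e1r,
                       double e2o, double e2r, double i0,
                       double noise_sd = 0.0) {
  const int n = hbo.nrow(), m = hbo.ncol();
  NumericMatrix i1(n, m), i2(n, m);
  for (int j = 0; j < m; ++j) {
    const double p = path[j];
    const double *po = &hbo(0, j), *pr = &hbr(0, j);
    double *q1 = &i1(0, j), *q2 = &i2(0, j);
    for (int i = 0; i < n; ++i) {
      const double o = po[i], r = pr[i];
      q1[i] = i0 * std::exp(-(e1o * o + e1r * r) * p);
      q2[i] = i0 * std::exp(-(e2o * o + e2r * r) * p);
    }
  }
  if (noise_sd > 0.0) {
    // Marsaglia polar normals driven by R's uniform RNG: deterministic
    // given the R seed, ~2x faster than inversion at this volume
    double spare = 0.0;
    bool have_spare = false;
    auto fast_norm = [&]() -> double {
      if (have_spare) { have_spare = false; return spare; }
      double u, v, s;
      do {
        u = 2.0 * unif_rand() - 1.0;
        v = 2.0 * unif_rand() - 1.0;
        s = u * u + v * v;
      } while (s >= 1.0 || s == 0.0);
      const double f = std::sqrt(-2.0 * std::log(s) / s);
      spare = v * f;
      have_spare = true;
      return u * f;
    };
    double *q1 = &i1(0, 0), *q2 = &i2(0, 0);
    const R_xlen_t len = (R_xlen_t)n * m;
    for (R_xlen_t i = 0; i < len; ++i) q1[i] += fast_norm() * noise_sd;
    for (R_xlen_t i = 0; i < len; ++i) q2[i] += fast_norm() * noise_sd;
  }
  return List::create(i1, i2);
}

// Column maxima.
// [[Rcpp::export(rng = false)]]
NumericVector col_max(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double *p = &x(0, j);
    double mx = p[0];
    for (int i = 1; i < n; ++i) if (p[i] > mx) mx = p[i];
    out[j] = mx;
  }
  return out;
}

// FIR smoothing of each column with an odd-length kernel, reflect-padded
// edges (same-length output).
// [[Rcpp::export(rng = false)]]
NumericMatrix fir_reflect(NumericMatrix x, NumericVector kernel) {
  const int n = x.nrow(), m = x.ncol(), k = kernel.size();
  const int h = (k - 1) / 2;
  NumericMatrix out(n, m);
  std::vector<double> pad(n + 2 * h);
  for (int j = 0; j < m; ++j) {
    const double *p = &x(0, j);
    for (int i = 0; i < h; ++i) pad[i] = p[h - i];
    std::copy(p, p + n, pad.begin() + h);
    for (int i = 0; i < h; ++i) pad[n + h + i] = p[n - 2 - i];
    double *q = &out(0, j);
    const double *kp = &kernel[0];
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const double *pp = &pad[i];
      for (int t = 0; t < k; ++t) s += pp[t] * kp[t];
      q[i] = s;
    }
  }
  return out;
}

// OD change on a flat column-major array with `n` samples per series
// (no reshaping copies).
// [[Rcpp::export(rng = false)]]
NumericVector od_convert_flat(NumericVector x, int n) {
  const R_xlen_t len = x.size();
  const R_xlen_t m = len / n;
  NumericVector out(no_init(len));
  const double *p0 = &x[0];
  double *q0 = &out[0];
  for (R_xlen_t j = 0; j < m; ++j) {
    const double *p = p0 + j * n;
    double *q = q0 + j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += p[i];
    const double lm = std::log(s / n);
    for (int i = 0; i < n; ++i) q[i] = lm - std::log(p[i]);
  }
  return out;
}

// OD change: -log(x / colmean(x)) per column, strictly positive input.
// [[Rcpp::export(rng = false)]]
NumericMatrix od_convert(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double *p = &x(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += p[i];
    const double lm = std::log(s / n);
    double *q = &out(0, j);
    for (int i = 0; i < n; ++i) q[i] = lm - std::log(p[i]);
  }
  return out;
}

// Motion-detection statistic: difference of adjacent w-sample means of a
// cw-sample centered moving average, |right - left|, per column. Edges
// clamp to the series boundary.
// [[Rcpp::export(rng = false)]]
NumericMatrix detect_stat(NumericMatrix x, int w, int cw) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  std::vector<double> cs(n + 1), cs2(n + 1);
  const int h2 = cw / 2;
  for (int j = 0; j < m; ++j) {
    const double *p = &x(0, j);
    cs[0] = 0.0;
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + p[i];
    // centered moving average with clamped edges
    cs2[0] = 0.0;
    for (int i = 0; i < n; ++i) {
      const int lo = std::max(i - h2, 0);
      const int hi = std::min(i + (cw - h2), n);
      cs2[i + 1] = cs2[i] + (cs[hi] - cs[lo]) / (hi - lo);
    }
    double *q = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const int lo = std::max(i + 1 - w, 0);
      const int hi = std::min(i + 1 + w, n);
      const double left = (cs2[i + 1] - cs2[lo]) / std::max(i + 1 - lo, 1);
      const double right = (cs2[hi] - cs2[i + 1]) / std::max(hi - i - 1, 1);
      q[i] = std::fabs(right - left);
    }
  }
  return out;
}

// natural cubic spline through (t, y), evaluated at 0..len-1 into out
static void natural_spline_eval(const std::vector<double> &t,
                                const std::vector<double> &y, int len,
                                std::vector<double> &out) {
  const int k = (int)t.size();
  if (k == 1) {
    std::fill(out.begin(), out.begin() + len, y[0]);
    return;
  }
  std::vector<double> m(k, 0.0);
  if (k > 2) {
    std::vector<double> h(k - 1), mu(k, 0.0), z(k, 0.0);
    for (int i = 0; i < k - 1; ++i) h[i] = t[i + 1] - t[i];
    double l0 = 1.0;
    for (int i = 1; i < k - 1; ++i) {
      const double alpha = 3.0 * ((y[i + 1] - y[i]) / h[i] -
                                  (y[i] - y[i - 1]) / h[i - 1]);
      const double li = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
      mu[i] = h[i] / li;
      z[i] = (alpha - h[i - 1] * z[i - 1]) / li;
      (void)l0;
    }
    for (int i = k - 2; i >= 1; --i) m[i] = z[i] - mu[i] * m[i + 1];
  }
  int seg = 0;
  for (int i = 0; i < len; ++i) {
    const double ti = (double)i;
    while (seg < k - 2 && ti > t[seg + 1]) ++seg;
    const double h = t[seg + 1] - t[seg];
    const double a = (t[seg + 1] - ti) / h, b = (ti - t[seg]) / h;
    out[i] = a * y[seg] + b * y[seg + 1] +
      ((a * a * a - a) * m[seg] + (b * b * b - b) * m[seg + 1]) *
        (h * h) / 6.0;
  }
}

// Spline correction of flagged segments, vectorized over columns.
// x: [time x series] (flagged series only); rng: detection statistic for
// those series; scale: per-series threshold. Flagged runs are dilated by
// `dil` samples, merged, fit by a natural cubic spline through local means
// on `kw`-sample knots, the spline subtracted, the segment re-leveled to
// the preceding `wl`-sample mean, and the subsequent signal shifted to
// remove any residual step.
// [[Rcpp::export(rng = false)]]
List correct_segments(NumericMatrix x, NumericMatrix rng,
                      NumericVector scale, int dil, int wl, int kw) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out = clone(x);
  int nseg = 0;
  std::vector<int> sa, sb;
  std::vector<double> kt, kv, fit(n);
  for (int j = 0; j < m; ++j) {
    const double *rj = &rng(0, j);
    const double thr = scale[j];
    double *xc = &out(0, j);
    // flagged runs, dilated and merged
    sa.clear(); sb.clear();
    int i = 0;
    while (i < n) {
      if (rj[i] > thr) {
        int a = i;
        while (i < n && rj[i] > thr) ++i;
        int b = i - 1;
        a = std::max(a - dil, 0);
        b = std::min(b + dil, n - 1);
        if (!sa.empty() && a <= sb.back() + 1) {
          sb.back() = std::max(sb.back(), b);
        } else {
          sa.push_back(a); sb.push_back(b);
        }
      } else ++i;
    }
    for (size_t s = 0; s < sa.size(); ++s) {
      const int a = sa[s], b = sb[s], len = b - a + 1;
      if (len >= 8) {
        kt.clear(); kv.clear();
        for (int k = 0; k < len; k += kw) kt.push_back((double)k);
        if (kt.back() != len - 1) kt.push_back((double)(len - 1));
        for (size_t q = 0; q < kt.size(); ++q) {
          const int kc = (int)kt[q];
          const int lo = std::max(0, kc - kw / 2);
          const int hi = std::min(len - 1, kc + kw / 2);
          double sm = 0.0;
          for (int t = lo; t <= hi; ++t) sm += xc[a + t];
          kv.push_back(sm / (hi - lo + 1));
        }
        natural_spline_eval(kt, kv, len, fit);
      } else {
        double sm = 0.0;
        for (int t = a; t <= b; ++t) sm += xc[t];
        std::fill(fit.begin(), fit.begin() + len, sm / len);
      }
      double rmean = 0.0;
      for (int t = 0; t < len; ++t) rmean += xc[a + t] - fit[t];
      rmean /= len;
      double pre;
      if (a > 0) {
        const int lo = std::max(0, a - wl);
        pre = 0.0;
        for (int t = lo; t < a; ++t) pre += xc[t];
        pre /= (a - lo);
      } else {
        pre = fit[0];
      }
      for (int t = 0; t < len; ++t)
        xc[a + t] = (xc[a + t] - fit[t]) - rmean + pre;
      if (b < n - 1) {
        const int hi = std::min(n - 1, b + wl);
        double post = 0.0;
        for (int t = b + 1; t <= hi; ++t) post += xc[t];
        post /= (hi - b);
        const int lo = std::max(0, len - wl);
        double tail = 0.0;
        for (int t = lo; t < len; ++t) tail += xc[a + t];
        tail /= (len - lo);
        const double jump = post - tail;
        for (int t = b + 1; t < n; ++t) xc[t] -= jump;
      }
      ++nseg;
    }
  }
  return List::create(out, nseg);
}

static double median_of(std::vector<double> &v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.begin() + n / 2);
  return 0.5 * (hi + v[n / 2 - 1]);
}

// Per-column median, over every `stride`-th row.
// [[Rcpp::export(rng = false)]]
NumericVector col_median(NumericMatrix x, int stride = 1) {
  const int n = x.nrow(), m = x.ncol();
  const int ns = (n + stride - 1) / stride;
  NumericVector out(m);
  std::vector<double> v(ns);
  for (int j = 0; j < m; ++j) {
    const double *p = &x(0, j);
    for (int i = 0; i < ns; ++i) v[i] = p[i * stride];
    out[j] = median_of(v);
  }
  return out;
}

// Per-column median absolute deviation about the median (unscaled), over
// every `stride`-th row.
// [[Rcpp::export(rng = false)]]
NumericVector col_mad(NumericMatrix x, int stride = 1) {
  const int n = x.nrow(), m = x.ncol();
  const int ns = (n + stride - 1) / stride;
  NumericVector out(m);
  std::vector<double> v(ns), d(ns);
  for (int j = 0; j < m; ++j) {
    const double *p = &x(0, j);
    for (int i = 0; i < ns; ++i) v[i] = p[i * stride];
    d = v;
    const double md = median_of(v);
    for (int i = 0; i < ns; ++i) d[i] = std::fabs(d[i] - md);
    out[j] = median_of(d);
  }
  return out;
}

// Per-column median of |first differences| over every `stride`-th row pair.
// [[Rcpp::export(rng = false)]]
NumericVector col_median_abs_diff(NumericMatrix x, int stride = 1) {
  const int n = x.nrow(), m = x.ncol();
  const int ns = (n - 1 + stride - 1) / stride;
  NumericVector out(m);
  std::vector<double> v(ns);
  for (int j = 0; j < m; ++j) {
    const double *p = &x(0, j);
    for (int i = 0; i < ns; ++i) {
      const int k = i * stride;
      v[i] = std::fabs(p[k + 1] - p[k]);
    }
    out[j] = median_of(v);
  }
  return out;
}
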