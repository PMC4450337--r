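#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sampling of img at (r, c) coordinate matrices (1-based, doubles).
// Out-of-domain coordinates clamp to the edge (replication), which keeps
// sampled intensities inside the observed range.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_sample(const NumericMatrix& img,
                                  const NumericMatrix& r,
                                  const NumericMatrix& c) {
  const int nr = img.nrow(), nc = img.ncol();
  const int onr = r.nrow(), onc = r.ncol();
  NumericMatrix out(onr, onc);
  for (int j = 0; j < onc; ++j) {
    for (int i = 0; i < onr; ++i) {
      double ri = r(i, j), ci = c(i, j);
      if (ri < 1.0) ri = 1.0; else if (ri > nr) ri = nr;
      if (ci < 1.0) ci = 1.0; else if (ci > nc) ci = nc;
      int r0 = (int)std::floor(ri); if (r0 > nr - 1) r0 = nr - 1; if (r0 < 1) r0 = 1;
      int c0 = (int)std::floor(ci); if (c0 > nc - 1) c0 = nc - 1; if (c0 < 1) c0 = 1;
      int r1 = r0 + 1, c1 = c0 + 1;
      double fr = ri - r0, fc = ci - c0;
      double v00 = img(r0 - 1, c0 - 1), v01 = img(r0 - 1, c1 - 1);
      double v10 = img(r1 - 1, c0 - 1), v11 = img(r1 - 1, c1 - 1);
      out(i, j) = (1 - fr) * ((1 - fc) * v00 + fc * v01)
                + fr       * ((1 - fc) * v10 + fc * v11);
    }
  }
  return out;
}

// Nearest-neighbour sampling with the same clamping rule.
// [[Rcpp::export]]
NumericMatrix cpp_nearest_sample(const NumericMatrix& img,
                                 const NumericMatrix& r,
                                 const NumericMatrix& c) {
  const int nr = img.nrow(), nc = img.ncol();
  const int onr = r.nrow(), onc = r.ncol();
  NumericMatrix out(onr, onc);
  for (int j = 0; j < onc; ++j) {
    for (int i = 0; i < onr; ++i) {
      int ri = (int)std::lround(r(i, j));
      int ci = (int)std::lround(c(i, j));
      if (ri < 1) ri = 1; else if (ri > nr) ri = nr;
      if (ci < 1) ci = 1; else if (ci > nc) ci = nc;
      out(i, j) = img(ri - 1, ci - 1);
    }
  }
  return out;
}

// Valid cross-correlation: out[i,j] = sum_{a,b} x[i+a, j+b] * k[a,b].
// Also the kernel-gradient of itself: d/dk = cpp_corr2_valid(x, delta).
// [[Rcpp::export]]
NumericMatrix cpp_corr2_valid(const NumericMatrix& x, const NumericMatrix& k) {
  const int nx = x.nrow(), mx = x.ncol();
  const int nk = k.nrow(), mk = k.ncol();
  const int no = nx - nk + 1, mo = mx - mk + 1;
  if (no < 1 || mo < 1) stop("kernel larger than input map");
  NumericMatrix out(no, mo);
  for (int b = 0; b < mk; ++b) {
    for (int a = 0; a < nk; ++a) {
      const double w = k(a, b);
      if (w == 0.0) continue;
      for (int j = 0; j < mo; ++j) {
        const double* xc = &x(a, j + b);
        double* oc = &out(0, j);
        for (int i = 0; i < no; ++i) oc[i] += w * xc[i];
      }
    }
  }
  return out;
}

// Full convolution: out[p,q] = sum_{a,b} g[p-a, q-b] * k[a,b] (zero outside).
// This is the input-gradient of cpp_corr2_valid.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_full(const NumericMatrix& g, const NumericMatrix& k) {
  const int ng = g.nrow(), mg = g.ncol();
  const int nk = k.nrow(), mk = k.ncol();
  const int no = ng + nk - 1, mo = mg + mk - 1;
  NumericMatrix out(no, mo);
  for (int b = 0; b < mk; ++b) {
    for (int a = 0; a < nk; ++a) {
      const double w = k(a, b);
      if (w == 0.0) continue;
      for (int j = 0; j < mg; ++j) {
        const double* gc = &g(0, j);
        double* oc = &out(a, j + b);
        for (int i = 0; i < ng; ++i) oc[i] += w * gc[i];
      }
    }
  }
  return out;
}

static inline int reflect_idx(int i, int n) {
  // mirror without edge repetition: ... 2 1 0 | 0 1 2 ... (scipy 'reflect')
  if (n == 1) return 0;
  const int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Separable convolution (rows then columns) with reflect boundary.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv_reflect(const NumericMatrix& x, const NumericVector& k) {
  const int nr = x.nrow(), nc = x.ncol(), nk = k.size();
  const int half = nk / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)            // along rows (vertical)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int a = 0; a < nk; ++a)
        s += k[a] * x(reflect_idx(i + a - half, nr), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < nc; ++j)            // along columns (horizontal)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int a = 0; a < nk; ++a)
        s += k[a] * tmp(i, reflect_idx(j + a - half, nc));
      out(i, j) = s;
    }
  return out;
}

// Kendall tau-a: (concordant - discordant) / (n(n-1)/2); ties count zero.
// [[Rcpp::export]]
double cpp_kendall_tau_a(const NumericVector& x, const NumericVector& y) {
  const R_xlen_t n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (n < 2) stop("need at least 2 observations");
  long long s = 0;
  for (R_xlen_t i = 0; i < n - 1; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double p = dx * dy;
      if (p > 0) ++s; else if (p < 0) --s;
    }
  return (double)s / ((double)n * (n - 1) / 2.0);
}
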