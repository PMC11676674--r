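// Fast pixel kernels for field-scale images: separable Gaussian blur, a 3x3
// median filter, and fused shot/read noise. Borders use replicate padding.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".gaussBlurC")]]
NumericMatrix gauss_blur(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* src = img.begin();
  double* t = tmp.begin();
  // vertical pass (within columns, unit stride)
  for (int j = 0; j < nc; ++j) {
    const double* col = src + (size_t)j * nr;
    double* tc = t + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      if (i >= r && i < nr - r) {
        const double* p = col + i - r;
        for (int d = 0; d <= 2 * r; ++d) acc += k[d] * p[d];
      } else {
        for (int d = -r; d <= r; ++d) {
          int ii = i + d;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          acc += k[d + r] * col[ii];
        }
      }
      tc[i] = acc;
    }
  }
  // horizontal pass (across columns)
  double* o = out.begin();
  for (int j = 0; j < nc; ++j) {
    double* oc = o + (size_t)j * nr;
    std::fill(oc, oc + nr, 0.0);
    for (int d = -r; d <= r; ++d) {
      int jj = j + d;
      if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
      const double* tc = t + (size_t)jj * nr;
      const double kd = k[d + r];
      for (int i = 0; i < nr; ++i) oc[i] += kd * tc[i];
    }
  }
  return out;
}

// Poisson shot noise + Gaussian read noise + clamping in one pass, using
// R's RNG stream (deterministic under set.seed).
// [[Rcpp::export(name = ".shotNoiseC")]]
NumericMatrix shot_noise(const NumericMatrix& img, double poissonScale,
                         double gaussSd, double hi) {
  const size_t n = (size_t)img.nrow() * img.ncol();
  NumericMatrix out(img.nrow(), img.ncol());
  RNGScope scope;
  for (size_t i = 0; i < n; ++i) {
    double v = img[i];
    if (poissonScale > 0)
      v = R::rpois(std::max(v, 0.0) * poissonScale) / poissonScale;
    if (gaussSd > 0) v += R::norm_rand() * gaussSd;
    if (v < 0) v = 0; else if (v > hi) v = hi;
    out[i] = v;
  }
  return out;
}

// RMS of the Sobel gradient magnitude over the whole image (replicate
// padding at the borders).
// [[Rcpp::export(name = ".sobelRmsC")]]
double sobel_rms(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  if (nr < 3 || nc < 3) return 0.0;
  const double* s = img.begin();
  double acc = 0.0;
  for (int j = 0; j < nc; ++j) {
    const int jm = (j == 0) ? 0 : j - 1;
    const int jp = (j == nc - 1) ? j : j + 1;
    const double* a = s + (size_t)jm * nr;
    const double* b = s + (size_t)j * nr;
    const double* c = s + (size_t)jp * nr;
    for (int i = 0; i < nr; ++i) {
      const int im = (i == 0) ? 0 : i - 1;
      const int ip = (i == nr - 1) ? i : i + 1;
      const double gx = (a[ip] + 2 * b[ip] + c[ip]) -
                        (a[im] + 2 * b[im] + c[im]);
      const double gy = (c[im] + 2 * c[i] + c[ip]) -
                        (a[im] + 2 * a[i] + a[ip]);
      acc += gx * gx + gy * gy;
    }
  }
  return std::sqrt(acc / ((double)nr * nc));
}

static inline void mnmx(double& a, double& b) {
  const double lo = std::min(a, b), hi = std::max(a, b);
  a = lo; b = hi;
}

// median of 9 via a fixed comparison network
static inline double med9(double p0, double p1, double p2, double p3,
                          double p4, double p5, double p6, double p7,
                          double p8) {
  mnmx(p1, p2); mnmx(p4, p5); mnmx(p7, p8);
  mnmx(p0, p1); mnmx(p3, p4); mnmx(p6, p7);
  mnmx(p1, p2); mnmx(p4, p5); mnmx(p7, p8);
  mnmx(p0, p3); mnmx(p5, p8); mnmx(p4, p7);
  mnmx(p3, p6); mnmx(p1, p4); mnmx(p2, p5);
  mnmx(p4, p7); mnmx(p4, p2); mnmx(p6, p4);
  mnmx(p4, p2);
  return p4;
}

// [[Rcpp::export(name = ".median3C")]]
NumericMatrix median3(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double* src = img.begin();
  double* o = out.begin();
  for (int j = 0; j < nc; ++j) {
    const int jm = (j == 0) ? 0 : j - 1;
    const int jp = (j == nc - 1) ? j : j + 1;
    const double* a = src + (size_t)jm * nr;
    const double* b = src + (size_t)j * nr;
    const double* c = src + (size_t)jp * nr;
    double* oc = o + (size_t)j * nr;
    // interior rows: branch-free window
    for (int i = 1; i < nr - 1; ++i)
      oc[i] = med9(a[i - 1], a[i], a[i + 1], b[i - 1], b[i], b[i + 1],
                   c[i - 1], c[i], c[i + 1]);
    oc[0] = med9(a[0], a[0], a[1], b[0], b[0], b[1], c[0], c[0], c[1]);
    oc[nr - 1] = med9(a[nr - 2], a[nr - 1], a[nr - 1], b[nr - 2], b[nr - 1],
                      b[nr - 1], c[nr - 2], c[nr - 1], c[nr - 1]);
  }
  return out;
}
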