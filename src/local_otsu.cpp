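#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Otsu threshold bin for a histogram; returns -1 when degenerate
// (all mass in one bin). Threshold semantics: foreground = bin > k.
static int otsu_bin(const std::vector<int>& h, int levels, long n) {
  long occupied = 0;
  for (int i = 0; i < levels; ++i) if (h[i] > 0) ++occupied;
  if (occupied < 2) return -1;
  double mu_t = 0.0;
  for (int i = 0; i < levels; ++i) mu_t += (double)i * h[i];
  double w0 = 0.0, mu0 = 0.0, best = -1.0;
  int best_k = -1;
  for (int k = 0; k < levels - 1; ++k) {
    w0 += h[k];
    mu0 += (double)k * h[k];
    double w1 = (double)n - w0;
    if (w0 <= 0.0 || w1 <= 0.0) continue;
    // between-class variance: (mu_t*p0 - mu0)^2 / (p0*(1-p0)), normalized by n
    double p0 = w0 / (double)n;
    double m0 = mu0 / (double)n;
    double sb = mu_t / (double)n * p0 - m0;
    sb = sb * sb / (p0 * (1.0 - p0));
    if (sb > best) { best = sb; best_k = k; }
  }
  return best_k;
}

// [[Rcpp::export]]
NumericMatrix local_otsu_cpp(NumericMatrix image, int window, int levels) {
  const int nr = image.nrow(), nc = image.ncol();
  const int half = window / 2;
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < nr * nc; ++i) {
    double v = image[i];
    if (v < lo) lo = v;
    if (v > hi) hi = v;
  }
  NumericMatrix out(nr, nc);
  if (!(hi > lo)) return out;
  const double scale = (levels - 1) / (hi - lo);
  // pre-binned image
  std::vector<int> bin(nr * nc);
  for (int i = 0; i < nr * nc; ++i) {
    int b = (int)((image[i] - lo) * scale + 0.5);
    if (b < 0) b = 0;
    if (b >= levels) b = levels - 1;
    bin[i] = b;
  }
  std::vector<int> h(levels);
  for (int j = 0; j < nc; ++j) {
    const int c0 = std::max(0, j - half), c1 = std::min(nc - 1, j + half);
    // build histogram for window centred at (0, j)
    std::fill(h.begin(), h.end(), 0);
    int r0 = 0, r1 = std::min(nr - 1, half);
    long n = 0;
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) { ++h[bin[r + nr * c]]; ++n; }
    for (int i = 0; i < nr; ++i) {
      if (i > 0) {
        // slide window down one row: add row i+half, drop row i-1-half
        int add = i + half, drop = i - 1 - half;
        if (add < nr)
          for (int c = c0; c <= c1; ++c) { ++h[bin[add + nr * c]]; ++n; }
        if (drop >= 0)
          for (int c = c0; c <= c1; ++c) { --h[bin[drop + nr * c]]; --n; }
      }
      int k = otsu_bin(h, levels, n);
      if (k >= 0 && bin[i + nr * j] > k) out(i, j) = 1.0;
    }
  }
  return out;
}
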