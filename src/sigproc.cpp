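#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Zero-phase IIR filtering with second-order sections and a deterministic
// Gaussian noise core. Kept in C++ because cohort-scale simulation applies
// these to millions of samples.

namespace {

// steady-state initial conditions for one biquad (direct form II transposed),
// scaled later by the first input sample; classic lfilter_zi 2x2 solve.
void biquad_zi(const double *s, double zi[2]) {
  const double b0 = s[0], b1 = s[1], b2 = s[2], a1 = s[4], a2 = s[5];
  // Solve (I - A^T) z = B with A = [[-a1, 1], [-a2, 0]],
  // B = [b1 - a1*b0, b2 - a2*b0]
  const double m00 = 1.0 + a1, m01 = -1.0, m10 = a2, m11 = 1.0;
  const double B0 = b1 - a1 * b0, B1 = b2 - a2 * b0;
  const double det = m00 * m11 - m01 * m10;
  zi[0] = (B0 * m11 - B1 * m01) / det;
  zi[1] = (m00 * B1 - m10 * B0) / det;
}

// one pass of the SOS cascade over x (in place), zi scaled by x[0]
void sos_forward(double *x, const int n, const NumericMatrix &sos) {
  const int ns = sos.nrow();
  for (int s = 0; s < ns; ++s) {
    double coef[6];
    for (int j = 0; j < 6; ++j) coef[j] = sos(s, j);
    const double b0 = coef[0], b1 = coef[1], b2 = coef[2],
                 a1 = coef[4], a2 = coef[5];
    double zi[2];
    biquad_zi(coef, zi);
    double z0 = zi[0] * x[0], z1 = zi[1] * x[0];
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z0;
      z0 = b1 * xi - a1 * yi + z1;
      z1 = b2 * xi - a2 * yi;
      x[i] = yi;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".sosfiltfilt_mat")]]
NumericMatrix sosfiltfilt_mat(NumericMatrix x, NumericMatrix sos, int padlen) {
  const int n = x.nrow(), nc = x.ncol();
  if (n <= 1) stop("signal too short to filter");
  if (padlen >= n) padlen = n - 1;
  const int m = n + 2 * padlen;
  NumericMatrix out(n, nc);
  std::vector<double> buf(m);
  for (int c = 0; c < nc; ++c) {
    // odd (antisymmetric) extension at both ends
    for (int i = 0; i < padlen; ++i)
      buf[i] = 2.0 * x(0, c) - x(padlen - i, c);
    for (int i = 0; i < n; ++i) buf[padlen + i] = x(i, c);
    for (int i = 0; i < padlen; ++i)
      buf[padlen + n + i] = 2.0 * x(n - 1, c) - x(n - 2 - i, c);
    sos_forward(buf.data(), m, sos);
    std::reverse(buf.begin(), buf.end());
    sos_forward(buf.data(), m, sos);
    std::reverse(buf.begin(), buf.end());
    for (int i = 0; i < n; ++i) out(i, c) = buf[padlen + i];
  }
  return out;
}

namespace {

// splitmix64: tiny, seedable, platform-stable
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

} // namespace

// [[Rcpp::export(name = ".gauss_mat")]]
NumericMatrix gauss_mat(int n, int nc, double seed) {
  SplitMix64 rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n, nc);
  double *p = REAL(out);
  const R_xlen_t total = static_cast<R_xlen_t>(n) * nc;
  R_xlen_t i = 0;
  while (i < total) { // Marsaglia polar method
    const double u = 2.0 * rng.unif() - 1.0;
    const double v = 2.0 * rng.unif() - 1.0;
    const double s = u * u + v * v;
    if (s >= 1.0 || s == 0.0) continue;
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    p[i++] = u * f;
    if (i < total) p[i++] = v * f;
  }
  return out;
}
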