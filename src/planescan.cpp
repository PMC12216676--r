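// Fast path for the periodicity engine: project reciprocal-space nodes onto a
// direction, histogram the projections, normalise against a moving average,
// and score Fourier magnitudes on the unit-Rayleigh scale.  The R functions
// make_histogram()/normalize_histogram()/score_spectrum() implement the same
// algorithm step by step; equality of the two paths is asserted in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec gauss_kernel(double sigma) {
  int r = (int)std::ceil(4.0 * sigma);
  arma::vec k(2 * r + 1);
  for (int j = -r; j <= r; ++j)
    k(j + r) = std::exp(-0.5 * (double)j * (double)j / (sigma * sigma));
  return k;
}

// Normalised (edge-renormalised) Gaussian convolution of a count vector.
static arma::vec smooth_counts(const arma::vec& H, const arma::vec& ker) {
  int n = (int)H.n_elem;
  int r = ((int)ker.n_elem - 1) / 2;
  arma::vec p(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, w = 0.0;
    int jlo = std::max(0, i - r), jhi = std::min(n - 1, i + r);
    for (int j = jlo; j <= jhi; ++j) {
      double kk = ker(j - i + r);
      s += kk * H(j);
      w += kk;
    }
    p(i) = s / w;
  }
  return p;
}

struct Peak {
  double score;
  double freq;
};

// Single-direction pipeline.  expected_freq < 0 scans all unmasked
// frequencies; otherwise only a window of +-window_bins Fourier bins around
// the expected frequency (in angstrom) is searched.
static Peak peak_from_projection(const arma::vec& x, double bin_width,
                                 double sigma, double p_floor, double g_max,
                                 double min_period, double expected_freq,
                                 int window_bins, const arma::vec& ker) {
  Peak out;
  out.score = 0.0;
  out.freq = NA_REAL;
  int m = (int)x.n_elem;
  if (m < 2) return out;

  double mn = x.min(), mx = x.max();
  double range = mx - mn;
  int n;
  double lo;
  if (range <= 0.0) {
    n = 16;
    lo = mn - 8.0 * bin_width;
  } else {
    n = std::max(16, (int)std::ceil(range * 1.05 / bin_width));
    lo = mn - 0.025 * range;
  }

  arma::vec H(n, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    int idx = (int)std::floor((x(i) - lo) / bin_width);
    if (idx < 0) idx = 0;
    if (idx > n - 1) idx = n - 1;
    H(idx) += 1.0;
  }

  arma::vec p = smooth_counts(H, ker);
  arma::vec h(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    if (p(i) > p_floor) h(i) = (H(i) - p(i)) / std::sqrt(p(i));

  arma::cx_vec F = arma::fft(h);
  double scale = std::sqrt(2.0 / (double)n);
  double L = (double)n * bin_width;
  // strictly below Nyquist; k = 0 excluded
  int kmax = (n - 1) / 2;
  // low frequencies where the moving-average subtraction still passes more
  // than g_max of the signal are not Rayleigh-calibrated: mask them
  double kmin_transfer =
      (double)n * std::sqrt(-std::log(g_max) / (2.0 * M_PI * M_PI * sigma * sigma));

  int klo = 1, khi = kmax;
  if (expected_freq > 0.0) {
    double kexp = expected_freq * L;
    klo = std::max(klo, (int)std::ceil(kexp - (double)window_bins));
    khi = std::min(khi, (int)std::floor(kexp + (double)window_bins));
  }

  double best = -1.0;
  int bestk = -1;
  for (int k = klo; k <= khi; ++k) {
    if ((double)k < kmin_transfer) continue;
    double f = (double)k / L;
    if (f < min_period) continue;
    double mag = std::abs(F(k));
    if (mag > best) {
      best = mag;
      bestk = k;
    }
  }
  if (bestk < 0) return out;

  // parabolic interpolation of the peak on raw magnitudes
  double m0 = std::abs(F(bestk));
  double mmi = (bestk - 1 >= 1) ? std::abs(F(bestk - 1)) : m0;
  double mpl = (bestk + 1 <= kmax) ? std::abs(F(bestk + 1)) : m0;
  double denom = mmi - 2.0 * m0 + mpl;
  double delta = 0.0;
  if (denom < 0.0) {
    delta = 0.5 * (mmi - mpl) / denom;
    if (delta > 0.5) delta = 0.5;
    if (delta < -0.5) delta = -0.5;
  }
  double vertex = m0 - 0.25 * (mmi - mpl) * delta;
  out.score = scale * std::max(m0, vertex);
  out.freq = ((double)bestk + delta) / L;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_scan_directions(const arma::mat& Q, const arma::mat& D,
                                  double bin_width, double sigma,
                                  double p_floor, double g_max,
                                  double min_period) {
  arma::mat P = Q * D.t();  // N x M projections
  arma::vec ker = gauss_kernel(sigma);
  int M = (int)D.n_rows;
  NumericMatrix out(M, 2);
  for (int j = 0; j < M; ++j) {
    Peak pk = peak_from_projection(P.col(j), bin_width, sigma, p_floor, g_max,
                                   min_period, -1.0, 0, ker);
    out(j, 0) = pk.score;
    out(j, 1) = pk.freq;
  }
  colnames(out) = CharacterVector::create("score", "freq_A");
  return out;
}

// [[Rcpp::export]]
List cpp_peak_score(const arma::vec& proj, double bin_width, double sigma,
                    double p_floor, double g_max, double min_period,
                    double expected_freq, int window_bins) {
  arma::vec ker = gauss_kernel(sigma);
  Peak pk = peak_from_projection(proj, bin_width, sigma, p_floor, g_max,
                                 min_period, expected_freq, window_bins, ker);
  return List::create(_["score"] = pk.score, _["freq_A"] = pk.freq);
}

// [[Rcpp::export]]
arma::vec cpp_smooth_counts(const arma::vec& H, double sigma) {
  return smooth_counts(H, gauss_kernel(sigma));
}
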