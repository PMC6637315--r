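#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR filter.  Coefficients must be normalised
// so that a[0] == 1; zi is the initial delay-line state (length
// max(m-1, 1); pass zeros for a zero initial state).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int m = b.size();  // == a.size() after padding on the R side
  NumericVector y(n);
  std::vector<double> z(m > 1 ? m - 1 : 1, 0.0);
  for (int j = 0; j < std::min<int>(zi.size(), z.size()); ++j) z[j] = zi[j];
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int j = 0; j < m - 2; ++j) {
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    }
    if (m > 1) z[m - 2] = b[m - 1] * xi - a[m - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Sample-by-sample LMS adaptive FIR noise canceller.
//
// desired:   contaminated signal d(n)
// reference: noise reference x(n) (the ECG channel)
// taps:      filter length L
// mu:        adaptation step size
// normalized: use the power-normalised update mu/(eps + ||x||^2)
// guard:     abort when max|w| exceeds this bound (divergence detector)
//
// For n < L-1 the reference history is zero padded, so the output has the
// same length and alignment as the input.  Returns the error signal
// e(n) = d(n) - y(n) (the cleaned EMG), the artifact estimate y(n), and
// the final tap weights.
// [[Rcpp::export]]
List lms_cpp(NumericVector desired, NumericVector reference, int taps,
             double mu, bool normalized, double eps, double guard) {
  const int n = desired.size();
  NumericVector e(n), y(n);
  std::vector<double> w(taps, 0.0);
  std::vector<double> xbuf(taps, 0.0);  // xbuf[j] = x(n - j)
  double xpow = 0.0;                    // running ||x||^2 for NLMS
  int head = 0;                         // circular buffer head
  for (int i = 0; i < n; ++i) {
    head = (head == 0) ? taps - 1 : head - 1;
    xpow += reference[i] * reference[i] - xbuf[head] * xbuf[head];
    xbuf[head] = reference[i];
    double yi = 0.0;
    for (int j = 0; j < taps; ++j) {
      yi += w[j] * xbuf[(head + j) % taps];
    }
    const double ei = desired[i] - yi;
    const double step = normalized ? mu / (eps + xpow) : mu;
    const double g = step * ei;
    double wmax = 0.0;
    for (int j = 0; j < taps; ++j) {
      w[j] += g * xbuf[(head + j) % taps];
      const double aw = std::fabs(w[j]);
      if (aw > wmax) wmax = aw;
    }
    if (wmax > guard) {
      stop("LMS filter diverged at sample %d (max|w| = %g): "
           "reduce step_size or enable normalized mode", i + 1, wmax);
    }
    e[i] = ei;
    y[i] = yi;
  }
  return List::create(_["cleaned"] = e, _["artifact"] = y,
                      _["weights"] = NumericVector(w.begin(), w.end()));
}
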