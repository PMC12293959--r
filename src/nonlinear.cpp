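#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double sqdist_row(const NumericMatrix& x, int i, int j, int m) {
  double s = 0.0;
  for (int c = 0; c < m; ++c) {
    double d = x(i, c) - x(j, c);
    s += d * d;
  }
  return s;
}

// Rosenstein divergence curve: for each reference point (0-based indices in
// `refs`), find its nearest neighbour outside the Theiler window, then track
// the log of the pair distance over `fit_span` forward steps.  Returns the
// mean log-divergence curve d(k), k = 0..fit_span, plus the pair count per k.
// [[Rcpp::export(name = ".nn_divergence_cpp")]]
List nn_divergence_cpp(NumericMatrix traj, IntegerVector refs,
                       int theiler, int fit_span) {
  const int n = traj.nrow(), m = traj.ncol();
  const int last = n - fit_span;  // both ends of a pair must be trackable
  NumericVector curve(fit_span + 1);
  IntegerVector counts(fit_span + 1);
  int n_pairs = 0;

  for (int r = 0; r < refs.size(); ++r) {
    int i = refs[r];
    if (i < 0 || i >= last) continue;
    double best = R_PosInf;
    int bestj = -1;
    for (int j = 0; j < last; ++j) {
      if (std::abs(j - i) <= theiler) continue;
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        double d = traj(i, c) - traj(j, c);
        s += d * d;
        if (s >= best) break;  // early abandon: cannot beat current best
      }
      if (s > 0.0 && s < best) { best = s; bestj = j; }
    }
    if (bestj < 0) continue;
    ++n_pairs;
    for (int k = 0; k <= fit_span; ++k) {
      double d2 = sqdist_row(traj, i + k, bestj + k, m);
      if (d2 > 0.0) {
        curve[k] += 0.5 * std::log(d2);
        counts[k] += 1;
      }
    }
  }
  for (int k = 0; k <= fit_span; ++k)
    curve[k] = counts[k] > 0 ? curve[k] / counts[k] : NA_REAL;
  return List::create(_["curve"] = curve, _["counts"] = counts,
                      _["n_pairs"] = n_pairs);
}

// Kennel false-nearest-neighbour fractions for m = 1..m_max.  References are
// a subsample (0-based); neighbours are searched over every usable point.
// A neighbour is false when the extra-coordinate distance ratio exceeds r_tol
// or the (m+1)-dimensional distance exceeds a_tol times the signal SD.
// [[Rcpp::export(name = ".fnn_cpp")]]
NumericVector fnn_cpp(NumericVector x, int tau, int m_max,
                      double r_tol, double a_tol, int theiler, int n_ref) {
  const int n = x.size();
  const double sd_x = Rcpp::sd(x);
  NumericVector frac(m_max, NA_REAL);

  for (int m = 1; m <= m_max; ++m) {
    const int usable = n - m * tau;  // points having the (m+1)-th coordinate
    if (usable < 10) { frac[m - 1] = NA_REAL; continue; }
    int nr = std::min(n_ref, usable);
    int n_false = 0, n_tested = 0;
    for (int r = 0; r < nr; ++r) {
      int i = (int)((double)r * usable / nr);
      double best = R_PosInf;
      int bestj = -1;
      for (int j = 0; j < usable; ++j) {
        if (std::abs(j - i) <= theiler) continue;
        double s = 0.0;
        for (int c = 0; c < m; ++c) {
          double d = x[i + c * tau] - x[j + c * tau];
          s += d * d;
          if (s >= best) break;
        }
        if (s < best) { best = s; bestj = j; }
      }
      if (bestj < 0) continue;
      double rm = std::sqrt(best);
      double extra = std::fabs(x[i + m * tau] - x[bestj + m * tau]);
      bool is_false;
      if (rm > 0.0)
        is_false = (extra / rm > r_tol) ||
                   (std::sqrt(rm * rm + extra * extra) / sd_x > a_tol);
      else
        is_false = (extra / sd_x > a_tol);
      ++n_tested;
      if (is_false) ++n_false;
    }
    frac[m - 1] = n_tested > 0 ? (double)n_false / n_tested : NA_REAL;
  }
  return frac;
}

// Correlation sums C(r) over a set of radii for the (0-based) subsample
// `idx`, counting unordered pairs separated by more than the Theiler window
// in original time index.  `times` carries the original time index of each
// subsampled row.  Radii must be sorted increasing.
// [[Rcpp::export(name = ".corr_sum_cpp")]]
List corr_sum_cpp(NumericMatrix traj, IntegerVector idx, IntegerVector times,
                  NumericVector radii, int theiler) {
  const int ns = idx.size(), m = traj.ncol(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int t = 0; t < nr; ++t) r2[t] = radii[t] * radii[t];
  std::vector<double> hist(nr + 1, 0.0);
  double n_pairs = 0.0;

  const double r2max = r2[nr - 1];
  for (int a = 0; a < ns; ++a) {
    for (int b = a + 1; b < ns; ++b) {
      if (std::abs(times[b] - times[a]) <= theiler) continue;
      ++n_pairs;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double d = traj(idx[a], c) - traj(idx[b], c);
        d2 += d * d;
        if (d2 > r2max) break;  // beyond every radius: no bin update needed
      }
      if (d2 > r2max) continue;
      // first radius with r^2 >= d2  (pair counted as "within r")
      int pos = std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin();
      hist[pos] += 1.0;
    }
  }
  NumericVector csum(nr);
  double acc = 0.0;
  for (int t = 0; t < nr; ++t) {
    acc += hist[t];
    csum[t] = n_pairs > 0 ? acc / n_pairs : NA_REAL;
  }
  return List::create(_["C"] = csum, _["n_pairs"] = n_pairs);
}
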