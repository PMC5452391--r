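#include <Rcpp.h>
using namespace Rcpp;

// Residence time / time-to-return cores on a regularized trajectory.
// Discrete accounting: every located fix inside the focal circle contributes
// one sampling interval; an excursion is a run of consecutive slots outside
// the circle (missing slots count as outside, so a data gap longer than the
// cut-off ends residence instead of fabricating it).

// [[Rcpp::export(name = ".rt_core")]]
NumericVector rt_core(NumericVector x, NumericVector y,
                      double interval_h, double radius, double cutoff_h) {
  int n = x.size();
  NumericVector rt(n, NA_REAL);
  double r2 = radius * radius;
  int maxout = (int) std::floor(cutoff_h / interval_h); // runs longer than this end residence
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i])) continue;
    double inside_n = 1.0; // focal fix itself
    // forward
    int out = 0;
    for (int j = i + 1; j < n; ++j) {
      bool in = false;
      if (!NumericVector::is_na(x[j])) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        in = (dx * dx + dy * dy) <= r2;
      }
      if (in) { inside_n += 1.0; out = 0; }
      else { ++out; if (out > maxout) break; }
    }
    // backward
    out = 0;
    for (int j = i - 1; j >= 0; --j) {
      bool in = false;
      if (!NumericVector::is_na(x[j])) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        in = (dx * dx + dy * dy) <= r2;
      }
      if (in) { inside_n += 1.0; out = 0; }
      else { ++out; if (out > maxout) break; }
    }
    rt[i] = inside_n * interval_h;
  }
  return rt;
}

// First absence exceeding the cut-off that is followed by a re-entry; the
// value is the full duration of that absence. Locations with no qualifying
// absence-and-return yield NA.

// [[Rcpp::export(name = ".t2r_core")]]
NumericVector t2r_core(NumericVector x, NumericVector y,
                       double interval_h, double radius, double cutoff_h) {
  int n = x.size();
  NumericVector t2r(n, NA_REAL);
  double r2 = radius * radius;
  int minout = (int) std::floor(cutoff_h / interval_h); // absence must exceed this
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i])) continue;
    int out = 0;
    for (int j = i + 1; j < n; ++j) {
      bool in = false;
      if (!NumericVector::is_na(x[j])) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        in = (dx * dx + dy * dy) <= r2;
      }
      if (in) {
        if (out > minout) { t2r[i] = out * interval_h; break; }
        out = 0;
      } else {
        ++out;
      }
    }
  }
  return t2r;
}
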