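#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy.
//
// Templates of length m are x[i..i+m-1] for i = 0..n-m-1 (so that every
// m-template also extends to an (m+1)-template); counts are over unordered
// pairs i < j, self-matches excluded.  B = pairs matching at length m,
// A = pairs matching at length m+1.  chebyshev selects the max-coordinate
// metric; otherwise the full Euclidean norm over the template is compared
// against r.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r,
                                bool chebyshev) {
  const int n = x.size();
  const int nt = n - m;
  if (nt < 2) stop("series too short for template length m");
  double A = 0.0, B = 0.0;
  const double r2 = r * r;
  const double *px = x.begin();
  if (chebyshev && m == 2) {
    // dominant case: unrolled
    for (int i = 0; i < nt; ++i) {
      const double x0 = px[i], x1 = px[i + 1], x2 = px[i + 2];
      for (int j = i + 1; j < nt; ++j) {
        if (std::fabs(x0 - px[j]) <= r && std::fabs(x1 - px[j + 1]) <= r) {
          B += 1.0;
          if (std::fabs(x2 - px[j + 2]) <= r) A += 1.0;
        }
      }
    }
  } else {
    for (int i = 0; i < nt; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        if (chebyshev) {
          bool match = true;
          for (int k = 0; k < m; ++k) {
            if (std::fabs(px[i + k] - px[j + k]) > r) { match = false; break; }
          }
          if (match) {
            B += 1.0;
            if (std::fabs(px[i + m] - px[j + m]) <= r) A += 1.0;
          }
        } else {
          double s = 0.0;
          for (int k = 0; k < m; ++k) {
            const double d = px[i + k] - px[j + k];
            s += d * d;
            if (s > r2) break;
          }
          if (s <= r2) {
            B += 1.0;
            const double d = px[i + m] - px[j + m];
            if (s + d * d <= r2) A += 1.0;
          }
        }
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
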