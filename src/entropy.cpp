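#include <Rcpp.h>
using namespace Rcpp;

// Template-match pair counts for sample entropy (Richman-Moorman convention).
// Templates of length m start at i = 0..L-m-1 (0-based), so that the extended
// template of length m+1 also exists for every counted index. Pairs are
// unordered (i < j), self-matches excluded. Chebyshev (max-norm) distance.
// Returns c(B, A): B = pairs matching over m samples within r,
//                  A = those pairs also matching at the (m+1)-th sample.
// [[Rcpp::export]]
NumericVector sampen_pair_counts(NumericVector y, int m, double r) {
  const int L = y.size();
  const int n = L - m;  // number of usable template start indices
  double B = 0.0, A = 0.0;
  if (n < 2) return NumericVector::create(0.0, 0.0);
  const double *x = REAL(y);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool match = true;
      for (int u = 0; u < m; ++u) {
        double d = x[i + u] - x[j + u];
        if (d > r || d < -r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        double d = x[i + m] - x[j + m];
        if (d <= r && d >= -r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Ordinal-pattern tallies for permutation entropy, order m (delay 1).
// Each window of m consecutive samples is coded by its m*(m-1)/2 pairwise
// comparison bits (x[i+a] > x[i+b] for a < b), an injective code for ordinal
// patterns; ties resolve by index order (earlier sample ranks lower).
// Returns integer counts over the 2^(m*(m-1)/2) code slots (only m! occupied).
// [[Rcpp::export]]
IntegerVector ordinal_pattern_counts(NumericVector y, int m) {
  const int L = y.size();
  const int nbits = m * (m - 1) / 2;
  IntegerVector counts(1 << nbits);
  if (L < m) return counts;
  const double *x = REAL(y);
  for (int i = 0; i + m <= L; ++i) {
    int code = 0, bit = 0;
    for (int a = 0; a < m - 1; ++a)
      for (int b = a + 1; b < m; ++b, ++bit)
        if (x[i + a] > x[i + b]) code |= (1 << bit);
    counts[code] += 1;
  }
  return counts;
}
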