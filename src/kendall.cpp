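#include <Rcpp.h>
using namespace Rcpp;

// Pair counts for Kendall's tau-b: concordant, discordant, tied only in a,
// tied only in b. O(n^2) pair enumeration; n is at most a few thousand here.
// [[Rcpp::export]]
NumericVector kendall_pair_counts(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  double C = 0, D = 0, Ta = 0, Tb = 0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double da = a[i] - a[j];
      const double db = b[i] - b[j];
      if (da == 0 && db == 0) continue;  // tied in both: excluded everywhere
      if (da == 0) { Ta += 1; continue; }
      if (db == 0) { Tb += 1; continue; }
      if ((da > 0) == (db > 0)) C += 1; else D += 1;
    }
  }
  return NumericVector::create(C, D, Ta, Tb);
}

// Tie-free tau of a permutation against the identity ordering:
// tau = 1 - 4 * inversions / (n (n - 1)).
// [[Rcpp::export]]
double tau_vs_identity(IntegerVector perm) {
  const R_xlen_t n = perm.size();
  double inv = 0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const int pi = perm[i];
    for (R_xlen_t j = i + 1; j < n; ++j) {
      if (perm[j] < pi) inv += 1;
    }
  }
  return 1.0 - 4.0 * inv / (static_cast<double>(n) * (n - 1));
}
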