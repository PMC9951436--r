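#include <Rcpp.h>
using namespace Rcpp;

// Pair energies in arbitrary units: GC -3, AT -2, GT wobble -1.
// Positive return marks a non-pairable combination.
static inline double pair_e(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1.0;
  return 1.0;
}

// Minimum total energy over all nested secondary structures with hairpin
// loops of at least min_loop unpaired nucleotides (Nussinov-style DP with
// weighted pairs). Unpaired bases contribute 0, so the optimum is <= 0.
// [[Rcpp::export]]
double fold_min_energy(std::string s, int min_loop = 3) {
  int n = s.size();
  if (n < min_loop + 2) return 0.0;
  NumericMatrix E(n, n);  // zero-initialized; E(i,j)=0 for short intervals
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double e = pair_e(s[i], s[k]);
        if (e > 0) continue;
        double v = e + E(i + 1, k - 1) + (k < j ? E(k + 1, j) : 0.0);
        if (v < best) best = v;
      }
      E(i, j) = best;
    }
  }
  return E(0, n - 1);
}
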