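#include <Rcpp.h>
using namespace Rcpp;

// Minimum (most negative) energy of a single maximal complementary run of
// length >= min_run over all ungapped antiparallel offsets of two RNA
// sequences. Bases are encoded A=0, C=1, G=2, U=3. Along a duplex register
// the positions i (in s) and j (in t) satisfy i + j = const, with j
// decreasing as i increases (antiparallel pairing).
//
// Because every admissible pair energy is negative, the full maximal run is
// its own most negative sub-run, so a simple accumulate-and-reset walk per
// anti-diagonal suffices.

// [[Rcpp::export(name = ".duplex_min_dg")]]
double duplex_min_dg(IntegerVector s, IntegerVector t,
                     double e_gc, double e_au, double e_gu, int min_run) {
  const int n = s.size(), m = t.size();
  double E[4][4];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      E[a][b] = 1.0; // positive sentinel: not complementary
  E[2][1] = E[1][2] = e_gc; // G:C
  E[0][3] = E[3][0] = e_au; // A:U
  E[2][3] = E[3][2] = e_gu; // G:U wobble

  double best = 0.0;
  for (int k = 0; k <= n + m - 2; ++k) {
    int i0 = k - m + 1 > 0 ? k - m + 1 : 0;
    int i1 = k < n - 1 ? k : n - 1;
    double cur = 0.0;
    int runlen = 0;
    for (int i = i0; i <= i1; ++i) {
      int j = k - i;
      double e = E[s[i]][t[j]];
      if (e < 0.0) {
        cur += e;
        ++runlen;
        if (runlen >= min_run && cur < best) best = cur;
      } else {
        cur = 0.0;
        runlen = 0;
      }
    }
  }
  return best;
}
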