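#include <Rcpp.h>
#include <vector>
#include <string>

// Maximum number of nested base pairs (Watson-Crick + G.T/G.U wobble)
// with a minimum hairpin loop of `min_loop` unpaired bases. A pairing
// proxy for secondary-structure stability; not a thermodynamic energy.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

//' Maximum number of nested base pairs in a sequence
//'
//' Dynamic-programming pair maximization over Watson-Crick plus G-T
//' wobble pairs with a minimum hairpin loop, used as the pairing-score
//' proxy for secondary-structure stability in [global_utr_features()].
//'
//' @param seq DNA string over ACGT.
//' @param min_loop minimum number of unpaired bases in a hairpin loop
//'   (default 3).
//' @return integer: the maximum number of simultaneous nested pairs.
//' @export
// [[Rcpp::export]]
int nussinov_maxpairs(std::string seq, int min_loop = 3) {
  const int n = (int)seq.size();
  if (n < min_loop + 2) return 0;
  std::vector<int> M((size_t)n * n, 0);
  auto at = [&](int i, int j) -> int& { return M[(size_t)i * n + j]; };
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = at(i, j - 1);  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(seq[(size_t)k], seq[(size_t)j])) continue;
        int left = (k > i) ? at(i, k - 1) : 0;
        int inner = (k + 1 <= j - 1) ? at(k + 1, j - 1) : 0;
        int v = left + 1 + inner;
        if (v > best) best = v;
      }
      at(i, j) = best;
    }
  }
  return at(0, n - 1);
}
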