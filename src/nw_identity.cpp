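#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Needleman-Wunsch global alignment with match +1, mismatch 0 and a
// linear gap penalty of -1 per residue (end gaps included). Alongside the
// optimal score, computes the maximum number of identical aligned
// positions achievable by any score-optimal alignment (a second DP over
// the optimal-score DAG), so the reported identity does not depend on
// traceback tie-breaking.
//
// [[Rcpp::export(name = ".nw_identity_cpp")]]
List nw_identity_cpp(std::string a, std::string b) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0)
    stop("sequences must be non-empty");
  const int GAP = -1;
  std::vector<int> Sprev(n + 1), Scur(n + 1), Mprev(n + 1), Mcur(n + 1);
  for (int j = 0; j <= n; ++j) { Sprev[j] = GAP * j; Mprev[j] = 0; }
  for (int i = 1; i <= m; ++i) {
    Scur[0] = GAP * i; Mcur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      const int match = (a[i - 1] == b[j - 1]) ? 1 : 0;
      const int sd = Sprev[j - 1] + match;      // diagonal (aligned pair)
      const int su = Sprev[j] + GAP;            // gap in b
      const int sl = Scur[j - 1] + GAP;         // gap in a
      int best = sd > su ? sd : su;
      if (sl > best) best = sl;
      int mm = -1;
      if (sd == best) { int v = Mprev[j - 1] + match; if (v > mm) mm = v; }
      if (su == best) { int v = Mprev[j]; if (v > mm) mm = v; }
      if (sl == best) { int v = Mcur[j - 1]; if (v > mm) mm = v; }
      Scur[j] = best; Mcur[j] = mm;
    }
    std::swap(Sprev, Scur); std::swap(Mprev, Mcur);
  }
  return List::create(_["score"] = Sprev[n], _["matches"] = Mprev[n]);
}
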