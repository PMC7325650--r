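#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Quadratic-space Gotoh global alignment score with affine gaps.
// Gap of length L costs gap_open + gap_ext * L (same convention as the
// production aligner). Kept as an independent reference implementation:
// plain textbook recurrences, no vectorisation tricks.
// [[Rcpp::export(name = ".dp_align_score")]]
double dp_align_score(std::string a, std::string b, double match,
                      double mismatch, double gap_open, double gap_ext) {
  const double NEG = -1e18;
  size_t n = a.size(), m = b.size();
  std::vector<double> H_prev(m + 1), H(m + 1), F_prev(m + 1), F(m + 1);
  std::vector<double> E(m + 1);

  H_prev[0] = 0.0;
  F_prev[0] = NEG;
  for (size_t j = 1; j <= m; ++j) {
    H_prev[j] = -(gap_open + gap_ext * j);
    F_prev[j] = NEG;
  }
  for (size_t i = 1; i <= n; ++i) {
    H[0] = -(gap_open + gap_ext * i);
    E[0] = NEG;
    F[0] = std::max(H_prev[0] - gap_open - gap_ext, F_prev[0] - gap_ext);
    for (size_t j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      F[j] = std::max(H_prev[j] - gap_open - gap_ext, F_prev[j] - gap_ext);
      E[j] = std::max(H[j - 1] - gap_open - gap_ext, E[j - 1] - gap_ext);
      H[j] = std::max(H_prev[j - 1] + s, std::max(E[j], F[j]));
    }
    std::swap(H, H_prev);
    std::swap(F, F_prev);
  }
  return H_prev[m];
}
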