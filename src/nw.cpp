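#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap penalty.
// Traceback tie-break: diagonal > up (gap in b) > left (gap in a).
// [[Rcpp::export(name = ".nwAlign")]]
List nwAlign(std::string a, std::string b,
             double match, double mismatch, double gap) {
  const size_t n = a.size(), m = b.size();
  std::vector<double> F((n + 1) * (m + 1));
  const size_t W = m + 1;
  for (size_t i = 0; i <= n; ++i) F[i * W] = gap * (double)i;
  for (size_t j = 0; j <= m; ++j) F[j] = gap * (double)j;
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double d = F[(i - 1) * W + (j - 1)] + s;
      double u = F[(i - 1) * W + j] + gap;
      double l = F[i * W + (j - 1)] + gap;
      double best = d;
      if (u > best) best = u;
      if (l > best) best = l;
      F[i * W + j] = best;
    }
  }
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    double cur = F[i * W + j];
    if (i > 0 && j > 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (cur == F[(i - 1) * W + (j - 1)] + s) {
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        continue;
      }
    }
    if (i > 0 && cur == F[(i - 1) * W + j] + gap) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      continue;
    }
    ra.push_back('-');
    rb.push_back(b[j - 1]);
    --j;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = F[n * W + m],
                      _["aligned_a"] = ra, _["aligned_b"] = rb);
}
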