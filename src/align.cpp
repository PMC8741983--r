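#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// Gap of length L costs open + L * ext (open charged once).
// Returns the single best-scoring local alignment with traceback
// statistics: score, query/subject spans (1-based, inclusive),
// number of identical columns and total alignment columns (incl. gaps).
// [[Rcpp::export(name = ".sw_best")]]
List sw_best(std::string query, std::string subject,
             double match, double mismatch,
             double gap_open, double gap_ext) {
  int m = query.size(), n = subject.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0);
  const double NEG = -1e18;
  // row-major (m+1) x (n+1)
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG); // gap in query (consume subject)
  std::vector<double> F((m + 1) * (n + 1), NEG); // gap in subject (consume query)
  std::vector<signed char> ptr((m + 1) * (n + 1), 0); // 0 stop,1 diag,2 E,3 F
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      int id = i * (n + 1) + j;
      double e = std::max(H[id - 1] - gap_open - gap_ext,
                          E[id - 1] - gap_ext);
      double f = std::max(H[id - (n + 1)] - gap_open - gap_ext,
                          F[id - (n + 1)] - gap_ext);
      double s = (qc == subject[j - 1]) ? match : mismatch;
      double diag = H[id - (n + 1) - 1] + s;
      double h = 0.0; signed char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (e > h)    { h = e;    p = 2; }
      if (f > h)    { h = f;    p = 3; }
      H[id] = h; E[id] = e; F[id] = f; ptr[id] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0);
  // traceback
  int i = bi, j = bj;
  int matches = 0, cols = 0;
  int qend = bi, send = bj;
  while (i > 0 && j > 0) {
    int id = i * (n + 1) + j;
    signed char p = ptr[id];
    if (p == 0) break;
    if (p == 1) {
      ++cols;
      if (query[i - 1] == subject[j - 1]) ++matches;
      --i; --j;
    } else if (p == 2) {
      // walk back along the E gap run
      while (j > 0) {
        ++cols; --j;
        int id2 = i * (n + 1) + j;
        if (H[id2] - gap_open - gap_ext >= E[id2] - gap_ext) break;
      }
    } else { // p == 3
      while (i > 0) {
        ++cols; --i;
        int id2 = i * (n + 1) + j;
        if (H[id2] - gap_open - gap_ext >= F[id2] - gap_ext) break;
      }
    }
  }
  return List::create(_["score"] = best,
                      _["qstart"] = i + 1, _["qend"] = qend,
                      _["sstart"] = j + 1, _["send"] = send,
                      _["matches"] = matches, _["cols"] = cols);
}
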