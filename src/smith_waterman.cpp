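#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, Gotoh).
// A gap of length L costs gap_open + L * gap_extend, i.e. the first gapped
// base already pays open + extend.  This matches the convention used by
// Biostrings::pairwiseAlignment, which the test suite uses as an
// independent oracle.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string ref,
                  double match = 1.0, double mismatch = -1.0,
                  double gap_open = 2.0, double gap_extend = 1.0) {
  const int n = query.size(), m = ref.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0,
                        _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                        _["r_start"] = NA_INTEGER, _["r_end"] = NA_INTEGER);
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  // traceback: tbH 0 = stop, 1 = diag, 2 = E (gap in query row), 3 = F
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((n + 1) * (m + 1), 0); // 1 = open, 2 = extend
  std::vector<unsigned char> tbF((n + 1) * (m + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  const double open_cost = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = i * (m + 1) + j;
      const int kup = (i - 1) * (m + 1) + j;
      const int kleft = k - 1;
      const int kdiag = kup - 1;
      // E: gap in the query (consume ref base)
      double e_open = H[kleft] - open_cost, e_ext = E[kleft] - gap_extend;
      E[k] = (e_open >= e_ext) ? e_open : e_ext;
      tbE[k] = (e_open >= e_ext) ? 1 : 2;
      // F: gap in the reference (consume query base)
      double f_open = H[kup] - open_cost, f_ext = F[kup] - gap_extend;
      F[k] = (f_open >= f_ext) ? f_open : f_ext;
      tbF[k] = (f_open >= f_ext) ? 1 : 2;
      double s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      double diag = H[kdiag] + s;
      double h = 0.0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[k] > h) { h = E[k]; tb = 2; }
      if (F[k] > h) { h = F[k]; tb = 3; }
      H[k] = h; tbH[k] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0,
                        _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                        _["r_start"] = NA_INTEGER, _["r_end"] = NA_INTEGER);
  // traceback from (bi, bj) to the alignment start
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    const int k = i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[k];
      if (tb == 0) break;
      if (tb == 1) { --i; --j; }
      else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (tbE[k] == 1) state = 0;
      --j;
    } else {
      if (tbF[k] == 1) state = 0;
      --i;
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["r_start"] = j + 1, _["r_end"] = bj);
}
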