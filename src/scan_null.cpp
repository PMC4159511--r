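#include <Rcpp.h>
using namespace Rcpp;

// Batch APS/CPS window counter for the Monte-Carlo null.
//
// codes: n x L integer matrix of base codes (A=1, C=2, G=3, T=4), one
// window per row. pair_values: 64 double-strand APE sums indexed by
// (b1-1)*16 + (b2-1)*4 + b3, NA = undetermined. motif_codes: list of
// integer code vectors; the caller supplies motifs and reverse complements
// already expanded. Returns an n x 2 logical matrix: column 1, window
// contains >= 1 APS (maximal run of >= apelen determined negative APE
// values); column 2, window contains >= 1 CPS (a motif start m with
// span_end < m <= span_end + 1 + motifgap for some APS, span_end being the
// run end plus one flanking base).
// [[Rcpp::export]]
LogicalMatrix scan_windows_cpp(IntegerMatrix codes, NumericVector pair_values,
                               int apelen, List motif_codes, int motifgap) {
  const int n = codes.nrow(), L = codes.ncol();
  LogicalMatrix out(n, 2);
  if (L < 3) return out;

  const int nmot = motif_codes.size();
  std::vector< std::vector<int> > pats(nmot);
  for (int k = 0; k < nmot; ++k) {
    IntegerVector p = motif_codes[k];
    pats[k] = std::vector<int>(p.begin(), p.end());
  }

  std::vector<char> neg(L), mstart(L);
  for (int r = 0; r < n; ++r) {
    // negative-APE mask
    neg[0] = 0; neg[L - 1] = 0;
    for (int i = 1; i < L - 1; ++i) {
      int b1 = codes(r, i - 1), b2 = codes(r, i), b3 = codes(r, i + 1);
      if (b1 == NA_INTEGER || b2 == NA_INTEGER || b3 == NA_INTEGER) {
        neg[i] = 0;
        continue;
      }
      double v = pair_values[(b1 - 1) * 16 + (b2 - 1) * 4 + (b3 - 1)];
      neg[i] = (!ISNA(v) && v < 0.0) ? 1 : 0;
    }
    // motif start positions (union over patterns)
    std::fill(mstart.begin(), mstart.end(), 0);
    for (int k = 0; k < nmot; ++k) {
      const std::vector<int> &p = pats[k];
      const int plen = (int) p.size();
      for (int s = 0; s + plen <= L; ++s) {
        bool hit = true;
        for (int j = 0; j < plen; ++j) {
          if (codes(r, s + j) != p[j]) { hit = false; break; }
        }
        if (hit) mstart[s] = 1;
      }
    }
    // maximal negative runs and APS-motif coupling
    bool has_aps = false, has_cps = false;
    int run = 0;
    for (int i = 0; i < L; ++i) {
      if (neg[i]) {
        ++run;
        bool run_ends = (i == L - 1) || !neg[i + 1];
        if (run_ends && run >= apelen) {
          has_aps = true;
          int span_end = i + 1;  // 3' flanking base (may equal L at edge)
          int lo = span_end + 1, hi = span_end + 1 + motifgap;
          if (hi > L - 1) hi = L - 1;
          for (int m = lo; m <= hi; ++m) {
            if (mstart[m]) { has_cps = true; break; }
          }
        }
        if (run_ends) run = 0;
      } else {
        run = 0;
      }
      if (has_cps) break;
    }
    out(r, 0) = has_aps;
    out(r, 1) = has_cps;
  }
  return out;
}
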