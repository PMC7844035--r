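#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// EHH walk from a core in one direction; returns the trapezoidal integral
// of EHH over physical distance, truncated at the first point where EHH
// falls below `cutoff` (that trapezoid included) or before a gap larger
// than `max_gap`. The core allele joins haplotype identity from the first
// flanking step; EHH at the core itself is 1. Missing alleles (-1) make a
// haplotype a permanent singleton.
static double ihh_dir(const IntegerMatrix &H, const NumericVector &pos,
                      int core, int dir, double cutoff, double max_gap) {
  const int n = H.ncol();
  const int m = H.nrow();
  const double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> grp(n, 0), key(n), order(n);
  double prev_e = 1.0, prev_pos = pos[core], total = 0.0;
  // incorporate the core allele first (it splits identity for flanks)
  int j = core;
  bool first = true;
  while (j >= 0 && j < m) {
    // update groups with site j's alleles
    int ngrp = 0;
    for (int h = 0; h < n; ++h) {
      int al = H(j, h);
      if (al < 0) al = 2 + h;            // unique, permanent singleton
      key[h] = grp[h] * (n + 2) + al;
    }
    // compress keys to dense group ids (n is small; simple O(n^2) scan)
    for (int h = 0; h < n; ++h) {
      int g = -1;
      for (int h2 = 0; h2 < h; ++h2)
        if (key[h2] == key[h]) { g = order[h2]; break; }
      if (g < 0) g = ngrp++;
      order[h] = g;                      // stage new ids
    }
    for (int h = 0; h < n; ++h) grp[h] = order[h];
    // EHH value
    std::vector<int> cnt(ngrp, 0);
    for (int h = 0; h < n; ++h) cnt[grp[h]]++;
    double e = 0.0;
    for (int g = 0; g < ngrp; ++g) e += (double)cnt[g] * (cnt[g] - 1) / 2.0;
    e /= denom;
    if (!first) {
      double gap = std::abs(pos[j] - prev_pos);
      if (gap > max_gap) break;
      total += gap * (e + prev_e) / 2.0;
      prev_e = e; prev_pos = pos[j];
      if (e < cutoff) break;
    } else {
      // core point: EHH reported as 1; the core allele is already folded
      // into the identity state, so the first flank trapezoid runs from
      // (core, 1) to the flank EHH computed over {core..flank} sites
      first = false;
      prev_e = 1.0; prev_pos = pos[j];
      if (e == 0.0) break;               // fully collapsed at the core site
    }
    j += dir;
  }
  return total;
}

// [[Rcpp::export]]
NumericVector ihh_scan_cpp(IntegerMatrix H, NumericVector pos,
                           double cutoff, double max_gap) {
  const int m = H.nrow();
  NumericVector out(m);
  for (int core = 0; core < m; ++core)
    out[core] = ihh_dir(H, pos, core, +1, cutoff, max_gap) +
                ihh_dir(H, pos, core, -1, cutoff, max_gap);
  return out;
}
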