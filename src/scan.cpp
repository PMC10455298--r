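#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// A base pairs with itself only; 'N' never matches anything (counts as a
// mismatch on either side).
static inline bool base_eq(char a, char b) {
  return a == b && a != 'N';
}

// Exhaustive top-strand scan: every window of |read| bases in `genome` whose
// Hamming distance to `read` is <= max_mm. Returns a 2-column matrix
// (0-based position, mismatch count). The caller handles the bottom strand by
// passing the reverse complement of the read.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_mismatch(const std::string& genome,
                                const std::string& read,
                                int max_mm) {
  const int L = (int)genome.size(), l = (int)read.size();
  std::vector<int> pos, mm;
  for (int p = 0; p + l <= L; ++p) {
    int d = 0;
    for (int i = 0; i < l; ++i) {
      if (!base_eq(read[i], genome[p + i]) && ++d > max_mm) break;
    }
    if (d <= max_mm) { pos.push_back(p); mm.push_back(d); }
  }
  IntegerMatrix out((int)pos.size(), 2);
  for (int i = 0; i < (int)pos.size(); ++i) {
    out(i, 0) = pos[i];
    out(i, 1) = mm[i];
  }
  return out;
}

// TRUE for each read with at least one window at Hamming distance <= max_mm
// in any of `texts` (single orientation; caller supplies reverse complements
// for the bottom strand). Early exit on the first hit.
// [[Rcpp::export]]
LogicalVector cpp_any_match(CharacterVector reads,
                            CharacterVector texts,
                            int max_mm) {
  const int nr = reads.size(), nt = texts.size();
  std::vector<std::string> gs(nt);
  for (int j = 0; j < nt; ++j) gs[j] = as<std::string>(texts[j]);
  LogicalVector out(nr);
  for (int i = 0; i < nr; ++i) {
    const std::string r = as<std::string>(reads[i]);
    const int l = (int)r.size();
    bool found = false;
    for (int j = 0; j < nt && !found; ++j) {
      const std::string& g = gs[j];
      const int L = (int)g.size();
      for (int p = 0; p + l <= L && !found; ++p) {
        int d = 0;
        for (int k = 0; k < l; ++k) {
          if (!base_eq(r[k], g[p + k]) && ++d > max_mm) break;
        }
        if (d <= max_mm) found = true;
      }
    }
    out[i] = found;
  }
  return out;
}

// All 0-based positions where `pattern` occurs verbatim in `text`
// (overlapping occurrences included; 'N' never matches).
// [[Rcpp::export]]
IntegerVector cpp_find_occurrences(const std::string& text,
                                   const std::string& pattern) {
  const int L = (int)text.size(), l = (int)pattern.size();
  std::vector<int> pos;
  for (int p = 0; p + l <= L; ++p) {
    bool ok = true;
    for (int i = 0; i < l; ++i) {
      if (!base_eq(pattern[i], text[p + i])) { ok = false; break; }
    }
    if (ok) pos.push_back(p);
  }
  return wrap(pos);
}

// TRUE for each read occurring verbatim somewhere in any of `texts`
// (single orientation).
// [[Rcpp::export]]
LogicalVector cpp_contains(CharacterVector reads, CharacterVector texts) {
  const int nr = reads.size(), nt = texts.size();
  std::vector<std::string> gs(nt);
  for (int j = 0; j < nt; ++j) gs[j] = as<std::string>(texts[j]);
  LogicalVector out(nr);
  for (int i = 0; i < nr; ++i) {
    const std::string r = as<std::string>(reads[i]);
    const int l = (int)r.size();
    bool found = false;
    for (int j = 0; j < nt && !found; ++j) {
      const std::string& g = gs[j];
      const int L = (int)g.size();
      for (int p = 0; p + l <= L && !found; ++p) {
        bool ok = true;
        for (int k = 0; k < l; ++k) {
          if (!base_eq(r[k], g[p + k])) { ok = false; break; }
        }
        if (ok) found = true;
      }
    }
    out[i] = found;
  }
  return out;
}

// One arm of the circular-permutation test, on the orientation supplied.
// For every anchor p where the read's first k-mer equals g[p : p+k]:
//   * extend the match to the maximal prefix length m (read[0:m] == g[p:p+m]),
//   * let s = l - m (length of the relocated segment),
//   * accept iff s >= min_transfer, p >= s, and read[m:l] == g[p-s : p]
//     exactly (any other deviation from the genome disqualifies the read).
// Returns a 3-column matrix (anchor p, matched prefix m, relocated length s).
// [[Rcpp::export]]
IntegerMatrix cpp_permutation_arm(const std::string& genome,
                                  const std::string& read,
                                  int k, int min_transfer) {
  const int L = (int)genome.size(), l = (int)read.size();
  std::vector<int> anchors, ms, ss;
  if (l >= k + min_transfer && L >= k) {
    for (int p = 0; p + k <= L; ++p) {
      bool seed = true;
      for (int i = 0; i < k; ++i) {
        if (!base_eq(read[i], genome[p + i])) { seed = false; break; }
      }
      if (!seed) continue;
      int m = k;
      while (m < l && p + m < L && base_eq(read[m], genome[p + m])) ++m;
      const int s = l - m;
      if (s < min_transfer || p < s) continue;
      bool suffix = true;
      for (int i = 0; i < s; ++i) {
        if (!base_eq(read[m + i], genome[p - s + i])) { suffix = false; break; }
      }
      if (suffix) { anchors.push_back(p); ms.push_back(m); ss.push_back(s); }
    }
  }
  IntegerMatrix out((int)anchors.size(), 3);
  for (int i = 0; i < (int)anchors.size(); ++i) {
    out(i, 0) = anchors[i];
    out(i, 1) = ms[i];
    out(i, 2) = ss[i];
  }
  return out;
}
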