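#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// 3'-end adapter read-through scan: longest overlap of an adapter prefix
// with the read suffix, length >= min_overlap, mismatch fraction <=
// max_mismatch_rate. Returns, per read, the 0-based start of the match and
// the 1-based adapter index (-1 / 0 when none). Longest overlap wins (i.e.
// earliest start); ties across adapters go to the first adapter given.
// [[Rcpp::export]]
List detect_adapter_cpp(CharacterVector reads, CharacterVector adapters,
                        int min_overlap, double max_mismatch_rate) {
  std::vector<std::string> ads(adapters.size());
  for (int i = 0; i < adapters.size(); ++i)
    ads[i] = as<std::string>(adapters[i]);
  IntegerVector start(reads.size(), -1), which(reads.size(), 0);
  for (int r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    const int L = (int)read.size();
    int best_o = -1, best_a = -1;
    for (int a = 0; a < (int)ads.size(); ++a) {
      const std::string& ad = ads[a];
      int omax = std::min(L, (int)ad.size());
      for (int o = omax; o >= min_overlap; --o) {
        if (best_o >= o) break;  // cannot beat current best
        int allowed = (int)(max_mismatch_rate * o + 1e-9);
        int mm = 0;
        bool ok = true;
        for (int i = 0; i < o; ++i) {
          if (read[L - o + i] != ad[i]) {
            if (++mm > allowed) { ok = false; break; }
          }
        }
        if (ok) { best_o = o; best_a = a; break; }
      }
    }
    if (best_o > 0) {
      start[r] = L - best_o;
      which[r] = best_a + 1;
    }
  }
  return List::create(_["start"] = start, _["adapter"] = which);
}

// Longest ungapped suffix(x)/prefix(y) overlap with identity >= min_identity
// and length >= min_overlap; 0 when none qualifies.
// [[Rcpp::export]]
int best_overlap_cpp(std::string x, std::string y,
                     int min_overlap, double min_identity) {
  const int omax = std::min(x.size(), y.size());
  for (int o = omax; o >= min_overlap; --o) {
    int allowed = (int)((1.0 - min_identity) * o + 1e-9);
    int mm = 0;
    bool ok = true;
    for (int i = 0; i < o; ++i) {
      if (x[x.size() - o + i] != y[i]) {
        if (++mm > allowed) { ok = false; break; }
      }
    }
    if (ok) return o;
  }
  return 0;
}

// Hamming distance between equal-length strings (no early exit).
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector a, std::string b) {
  IntegerVector out(a.size());
  for (int i = 0; i < a.size(); ++i) {
    std::string s = as<std::string>(a[i]);
    if (s.size() != b.size()) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (size_t j = 0; j < s.size(); ++j)
      if (s[j] != b[j]) ++mm;
    out[i] = mm;
  }
  return out;
}
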