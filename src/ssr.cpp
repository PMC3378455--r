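#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smallest period of a motif; a motif whose smallest period divides its
// length and is < length is itself a repeat and is reported at that period.
static int smallest_period(const std::string& m) {
  const int p = (int)m.size();
  for (int d = 1; d < p; ++d) {
    if (p % d != 0) continue;
    bool ok = true;
    for (int i = d; i < p && ok; ++i)
      if (m[i] != m[i - d]) ok = false;
    if (ok) return d;
  }
  return p;
}

static inline bool acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Maximal perfect tandem repeats of unit size 1..length(min_repeats); a run
// is reported when it holds >= min_repeats[p] full units and its unit is not
// itself periodic (smallest-period rule).
// [[Rcpp::export]]
DataFrame find_ssrs_cpp(std::string seq, IntegerVector min_repeats) {
  const int L = (int)seq.size();
  const int maxp = min_repeats.size();
  std::vector<std::string> motifs;
  std::vector<int> nrep, starts, ends, periods;
  for (int p = 1; p <= maxp; ++p) {
    int thr = min_repeats[p - 1];
    int i = 0;
    while (i + p <= L) {
      // require a clean unit
      bool clean = true;
      for (int x = i; x < i + p; ++x)
        if (!acgt(seq[x])) { clean = false; i = x + 1; break; }
      if (!clean) continue;
      // extend the period-p self-match as far as it goes
      int e = i + p;
      while (e < L && acgt(seq[e]) && seq[e] == seq[e - p]) ++e;
      int reps = (e - i) / p;
      if (reps >= thr) {
        std::string motif = seq.substr(i, p);
        if (smallest_period(motif) == p) {
          motifs.push_back(motif);
          periods.push_back(p);
          nrep.push_back(reps);
          starts.push_back(i + 1);            // 1-based inclusive
          ends.push_back(i + p * reps);
        }
      }
      int nxt = e - p + 1;
      i = (nxt > i + 1) ? nxt : i + 1;
    }
  }
  return DataFrame::create(_["motif"] = motifs, _["period"] = periods,
                           _["n_repeats"] = nrep, _["start"] = starts,
                           _["end"] = ends,
                           _["stringsAsFactors"] = false);
}
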