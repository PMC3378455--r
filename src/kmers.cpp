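#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline bool acgt_b(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static std::string rc_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'T': r[i] = 'A'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      default: break;
    }
  }
  return r;
}

static inline std::string canon(const std::string& k) {
  std::string r = rc_str(k);
  return (r < k) ? r : k;
}

// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector seqs, int k, bool canonical) {
  std::unordered_map<std::string, int> tab;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    const int L = (int)seq.size();
    if (L < k) continue;
    int run = 0;  // clean bases ending at i
    for (int i = 0; i < L; ++i) {
      run = acgt_b(seq[i]) ? run + 1 : 0;
      if (run >= k) {
        std::string km = seq.substr(i - k + 1, k);
        if (canonical) km = canon(km);
        ++tab[km];
      }
    }
  }
  std::vector<std::string> keys;
  keys.reserve(tab.size());
  for (std::unordered_map<std::string, int>::iterator it = tab.begin();
       it != tab.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kk(keys.size());
  IntegerVector cc(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kk[i] = keys[i];
    cc[i] = tab[keys[i]];
  }
  return List::create(_["kmer"] = kk, _["count"] = cc);
}

// Median dataset frequency of each read's k-mers; k-mers absent from the
// table (including any containing non-ACGT) count as frequency 0.
// [[Rcpp::export]]
NumericVector read_median_kmer_freq_cpp(CharacterVector seqs, int k,
                                        CharacterVector kmers,
                                        IntegerVector counts,
                                        bool canonical) {
  std::unordered_map<std::string, int> tab;
  for (int i = 0; i < kmers.size(); ++i)
    tab[as<std::string>(kmers[i])] = counts[i];
  NumericVector out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    const int L = (int)seq.size();
    if (L < k) { out[s] = NA_REAL; continue; }
    std::vector<double> freqs;
    freqs.reserve(L - k + 1);
    for (int i = 0; i + k <= L; ++i) {
      std::string km = seq.substr(i, k);
      bool clean = true;
      for (int j = 0; j < k && clean; ++j)
        if (!acgt_b(km[j])) clean = false;
      if (!clean) { freqs.push_back(0.0); continue; }
      if (canonical) km = canon(km);
      std::unordered_map<std::string, int>::iterator it = tab.find(km);
      freqs.push_back(it == tab.end() ? 0.0 : (double)it->second);
    }
    std::sort(freqs.begin(), freqs.end());
    size_t n = freqs.size();
    out[s] = (n % 2 == 1) ? freqs[n / 2]
                          : 0.5 * (freqs[n / 2 - 1] + freqs[n / 2]);
  }
  return out;
}
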