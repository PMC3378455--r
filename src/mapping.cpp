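#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Seed width of the positional index used by the pigeonhole mapper.
#define SEED_W 11

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string revcomp_std(const std::string& s) {
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

struct Hit {
  int tid;     // 0-based transcript index
  int pos;     // 0-based offset on the transcript forward strand
  int strand;  // +1: read as given matches; -1: its reverse complement matches
  int mm;
};

static inline bool hit_less(const Hit& a, const Hit& b) {
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.tid != b.tid) return a.tid < b.tid;
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.strand > b.strand;  // '+' before '-'
}

// Count mismatches of read against t[start, start+len); early exit beyond cap.
// Any non-ACGT base is a mismatch even when the characters agree.
static inline int mm_count(const std::string& t, int start,
                           const std::string& read, int cap) {
  int mm = 0;
  const int L = (int)read.size();
  for (int i = 0; i < L; ++i) {
    char a = t[start + i], b = read[i];
    if (a != b || base_code(a) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

typedef std::unordered_map<uint32_t, std::vector<std::pair<int,int> > > SeedIndex;

static void index_transcripts(const std::vector<std::string>& txs, SeedIndex& idx) {
  for (size_t t = 0; t < txs.size(); ++t) {
    const std::string& s = txs[t];
    if ((int)s.size() < SEED_W) continue;
    uint32_t key = 0;
    int run = 0;  // valid bases accumulated in current window
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)c) & ((1u << (2 * SEED_W)) - 1u);
      if (++run >= SEED_W) {
        idx[key].push_back(std::make_pair((int)t, (int)(i - SEED_W + 1)));
      }
    }
  }
}

// Pack the SEED_W-mer starting at o; returns false when it contains non-ACGT.
static inline bool pack_seed(const std::string& r, int o, uint32_t& key) {
  key = 0;
  for (int i = 0; i < SEED_W; ++i) {
    int c = base_code(r[o + i]);
    if (c < 0) return false;
    key = (key << 2) | (uint32_t)c;
  }
  return true;
}

static void gather_seeded(const std::string& read, int strand,
                          const std::vector<std::string>& txs,
                          const SeedIndex& idx, int max_mm,
                          std::unordered_set<uint64_t>& seen,
                          std::vector<Hit>& hits) {
  const int L = (int)read.size();
  const int nseg = max_mm + 1;
  for (int j = 0; j < nseg; ++j) {
    int o = (int)(((long long)j * L) / nseg);
    uint32_t key;
    if (!pack_seed(read, o, key)) continue;
    SeedIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<std::pair<int,int> >& cands = it->second;
    for (size_t c = 0; c < cands.size(); ++c) {
      int tid = cands[c].first;
      int start = cands[c].second - o;
      if (start < 0 || start + L > (int)txs[tid].size()) continue;
      uint64_t kk = ((uint64_t)(strand > 0 ? 0 : 1) << 63) |
                    ((uint64_t)tid << 32) | (uint64_t)start;
      if (!seen.insert(kk).second) continue;
      int mm = mm_count(txs[tid], start, read, max_mm);
      if (mm <= max_mm) {
        Hit h; h.tid = tid; h.pos = start; h.strand = strand; h.mm = mm;
        hits.push_back(h);
      }
    }
  }
}

static List hits_to_result(std::vector<std::vector<Hit> >& all,
                           const std::vector<bool>& skipped,
                           bool report_all) {
  const int n = (int)all.size();
  if (report_all) {
    std::vector<int> rd, tid, pos, strand, mm;
    for (int i = 0; i < n; ++i) {
      std::sort(all[i].begin(), all[i].end(), hit_less);
      for (size_t j = 0; j < all[i].size(); ++j) {
        rd.push_back(i + 1);
        tid.push_back(all[i][j].tid + 1);
        pos.push_back(all[i][j].pos);
        strand.push_back(all[i][j].strand);
        mm.push_back(all[i][j].mm);
      }
    }
    return List::create(_["read"] = wrap(rd), _["tid"] = wrap(tid),
                        _["pos"] = wrap(pos), _["strand"] = wrap(strand),
                        _["mm"] = wrap(mm),
                        _["skipped"] = wrap(skipped));
  }
  IntegerVector tid(n, NA_INTEGER), pos(n, NA_INTEGER), mm(n, NA_INTEGER),
                strand(n, NA_INTEGER), n_best(n, 0), n_hits(n, 0);
  LogicalVector mapped(n, false), uniq(n, false), skip(n);
  for (int i = 0; i < n; ++i) {
    skip[i] = skipped[i];
    if (all[i].empty()) continue;
    std::sort(all[i].begin(), all[i].end(), hit_less);
    const Hit& b = all[i][0];
    int nb = 0;
    for (size_t j = 0; j < all[i].size(); ++j)
      if (all[i][j].mm == b.mm) ++nb;
    mapped[i] = true;
    tid[i] = b.tid + 1;
    pos[i] = b.pos;
    strand[i] = b.strand;
    mm[i] = b.mm;
    n_best[i] = nb;
    n_hits[i] = (int)all[i].size();
    uniq[i] = (nb == 1);
  }
  return List::create(_["mapped"] = mapped, _["tid"] = tid, _["pos"] = pos,
                      _["strand"] = strand, _["mm"] = mm,
                      _["n_best"] = n_best, _["n_hits"] = n_hits,
                      _["unique"] = uniq, _["skipped"] = skip);
}

// [[Rcpp::export]]
List ph_map_cpp(CharacterVector reads, CharacterVector transcripts,
                int max_mm, bool report_all) {
  std::vector<std::string> txs(transcripts.size());
  for (int i = 0; i < transcripts.size(); ++i)
    txs[i] = as<std::string>(transcripts[i]);
  SeedIndex idx;
  index_transcripts(txs, idx);
  const int n = reads.size();
  const int min_len = SEED_W * (max_mm + 1);
  std::vector<std::vector<Hit> > all(n);
  std::vector<bool> skipped(n, false);
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    if ((int)r.size() < min_len) { skipped[i] = true; continue; }
    seen.clear();
    gather_seeded(r, +1, txs, idx, max_mm, seen, all[i]);
    seen.clear();
    gather_seeded(revcomp_std(r), -1, txs, idx, max_mm, seen, all[i]);
  }
  return hits_to_result(all, skipped, report_all);
}

// Exhaustive scan over every (transcript, offset, strand); independent of the
// seeded path above, used as its oracle.
// [[Rcpp::export]]
List brute_map_cpp(CharacterVector reads, CharacterVector transcripts,
                   int max_mm, bool report_all) {
  std::vector<std::string> txs(transcripts.size());
  for (int i = 0; i < transcripts.size(); ++i)
    txs[i] = as<std::string>(transcripts[i]);
  const int n = reads.size();
  std::vector<std::vector<Hit> > all(n);
  std::vector<bool> skipped(n, false);
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp_std(fwd);
    const int L = (int)fwd.size();
    for (int t = 0; t < (int)txs.size(); ++t) {
      const std::string& tx = txs[t];
      if ((int)tx.size() < L) continue;
      for (int start = 0; start + L <= (int)tx.size(); ++start) {
        int mm = mm_count(tx, start, fwd, max_mm);
        if (mm <= max_mm) {
          Hit h; h.tid = t; h.pos = start; h.strand = +1; h.mm = mm;
          all[i].push_back(h);
        }
        mm = mm_count(tx, start, rev, max_mm);
        if (mm <= max_mm) {
          Hit h; h.tid = t; h.pos = start; h.strand = -1; h.mm = mm;
          all[i].push_back(h);
        }
      }
    }
  }
  return hits_to_result(all, skipped, report_all);
}
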