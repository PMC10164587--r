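#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// DNA alphabet: A=0 C=1 G=2 T=3, anything else = -1 (never matches, never seeds)
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// Seed-and-extend partial alignment: exact k-mer seeds taken from a reference
// index built every `step` positions (tile size `tile`), each seed extended to
// the maximal exact run containing it. Segments shorter than min_len matches
// are discarded. Coordinates are 0-based half-open.
// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector reads, CharacterVector refs,
                          int tile, int step, int min_len) {
  const uint64_t mask = (tile >= 32) ? ~0ULL : ((1ULL << (2 * tile)) - 1);
  std::vector<std::vector<int>> R(refs.size());
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  for (int t = 0; t < refs.size(); ++t) {
    R[t] = encode(as<std::string>(refs[t]));
    const std::vector<int>& r = R[t];
    for (int p = 0; p + tile <= (int)r.size(); p += step) {
      uint64_t key = 0; bool ok = true;
      for (int u = 0; u < tile; ++u) {
        if (r[p + u] < 0) { ok = false; break; }
        key = ((key << 2) | (uint64_t)r[p + u]) & mask;
      }
      if (ok) index[key].push_back(std::make_pair(t, p));
    }
  }
  std::vector<int> o_read, o_qs, o_qe, o_t, o_ts, o_te, o_m;
  for (int i = 0; i < reads.size(); ++i) {
    std::vector<int> q = encode(as<std::string>(reads[i]));
    int L = (int)q.size();
    if (L < tile) continue;
    // seen runs for this read: key (t, diag encoded, q_start)
    std::unordered_map<uint64_t, bool> seen;
    uint64_t key = 0; int valid = 0;
    for (int p = 0; p < L; ++p) {
      if (q[p] < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)q[p]) & mask;
      if (++valid < tile) continue;
      int qpos = p - tile + 1; // seed start in read
      auto hit = index.find(key);
      if (hit == index.end()) continue;
      for (size_t h = 0; h < hit->second.size(); ++h) {
        int t = hit->second[h].first, tpos = hit->second[h].second;
        const std::vector<int>& r = R[t];
        // extend left
        int qs = qpos, ts = tpos;
        while (qs > 0 && ts > 0 && q[qs - 1] >= 0 && q[qs - 1] == r[ts - 1]) { --qs; --ts; }
        // extend right
        int qe = qpos + tile, te = tpos + tile;
        while (qe < L && te < (int)r.size() && q[qe] >= 0 && q[qe] == r[te]) { ++qe; ++te; }
        int m = qe - qs;
        if (m < min_len) continue;
        uint64_t sig = ((uint64_t)(uint32_t)t << 40) ^
                       ((uint64_t)(uint32_t)ts << 16) ^ (uint64_t)(uint32_t)qs;
        if (seen.count(sig)) continue;
        seen[sig] = true;
        o_read.push_back(i + 1); o_qs.push_back(qs); o_qe.push_back(qe);
        o_t.push_back(t + 1); o_ts.push_back(ts); o_te.push_back(te);
        o_m.push_back(m);
      }
    }
  }
  return DataFrame::create(_["read"] = o_read, _["q_start"] = o_qs,
                           _["q_end"] = o_qe, _["t"] = o_t,
                           _["t_start"] = o_ts, _["t_end"] = o_te,
                           _["matches"] = o_m);
}
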