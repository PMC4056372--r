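#ifndef METACOLOR_DBG_H
#define METACOLOR_DBG_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <map>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>

// 2-bit base codes: A=0, C=1, G=2, T=3. With the first base of a word in the
// most-significant bits, unsigned integer order on packed words equals
// lexicographic order on the strings, so canonical = min(word, revcomp).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char code_base(int b) { return "ACGT"[b & 3]; }
static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

static inline uint64_t kmer_mask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static inline uint64_t revcomp_bits(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) { r = (r << 2) | (3ULL - (v & 3ULL)); v >>= 2; }
  return r;
}

static inline std::string decode_kmer(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = code_base((int)(v & 3ULL)); v >>= 2; }
  return s;
}

// returns -1 on success, else 0-based offset of first invalid character
static inline long encode_kmer(const std::string& s, uint64_t& out) {
  uint64_t v = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) return (long)i;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return -1;
}

static inline std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

// pure shard hash (splitmix64): keeps shard_of a deterministic function of
// the packed canonical word only
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct Vertex {
  uint16_t cov = 0;   // saturates at 65535
  uint8_t out = 0;    // bit (1<<b): canonical word extended by base b was observed
  uint8_t in = 0;     // bit (1<<b): canonical word preceded by base b was observed
  int32_t cs = 0;     // interned color-set id; 0 = empty set
};

struct DBG {
  int k;
  int S;
  std::vector<std::unordered_map<uint64_t, Vertex>> shards;
  // interned color sets: id -> sorted color ids; shared between vertices
  std::vector<std::vector<int>> color_sets;
  std::map<std::vector<int>, int> cs_index;
  uint64_t windows = 0;       // valid k-mer windows ingested
  uint64_t saturated = 0;     // coverage increments lost to saturation
  uint64_t skipped = 0;       // malformed records skipped

  DBG(int k_, int S_) : k(k_), S(S_), shards((size_t)S_) {
    color_sets.push_back(std::vector<int>());
    cs_index[color_sets[0]] = 0;
  }

  int shard_of(uint64_t km) const { return (int)(splitmix64(km) % (uint64_t)S); }

  Vertex* find(uint64_t km) {
    auto& m = shards[(size_t)shard_of(km)];
    auto it = m.find(km);
    return it == m.end() ? (Vertex*)0 : &it->second;
  }
  const Vertex* find(uint64_t km) const {
    const auto& m = shards[(size_t)shard_of(km)];
    auto it = m.find(km);
    return it == m.end() ? (const Vertex*)0 : &it->second;
  }

  Vertex& at_insert(uint64_t km) { return shards[(size_t)shard_of(km)][km]; }

  size_t size() const {
    size_t n = 0;
    for (const auto& m : shards) n += m.size();
    return n;
  }

  int intern_with(int cs_id, int color) {
    std::vector<int> v = color_sets[(size_t)cs_id];
    auto pos = std::lower_bound(v.begin(), v.end(), color);
    if (pos != v.end() && *pos == color) return cs_id;
    v.insert(pos, color);
    auto it = cs_index.find(v);
    if (it != cs_index.end()) return it->second;
    int id = (int)color_sets.size();
    color_sets.push_back(v);
    cs_index[v] = id;
    return id;
  }
};

// Oriented traversal: a path position is (canonical kmer, orient).
// orient = true: the walk reads the canonical word as stored;
// orient = false: the walk reads its reverse complement.
struct Oriented { uint64_t km; bool fwd; };

// word as read in walk direction
static inline uint64_t walk_word(const DBG& g, const Oriented& o) {
  return o.fwd ? o.km : revcomp_bits(o.km, g.k);
}

// successors of an oriented vertex along the walk direction, restricted to
// marked edges; does not check target presence (caller filters)
static inline void walk_successors(const DBG& g, const Oriented& o, const Vertex& v,
                                   std::vector<std::pair<int, Oriented>>& out) {
  out.clear();
  uint8_t mask = o.fwd ? v.out : v.in;
  uint64_t w = walk_word(g, o);
  uint64_t mk = kmer_mask(g.k);
  for (int b = 0; b < 4; ++b) {
    int bit = o.fwd ? b : (3 - b);  // in-mask stores the preceding base of the canonical word
    if (!(mask & (1u << bit))) continue;
    uint64_t nw = ((w << 2) | (uint64_t)b) & mk;
    uint64_t rc = revcomp_bits(nw, g.k);
    Oriented nx;
    if (nw <= rc) { nx.km = nw; nx.fwd = true; }
    else { nx.km = rc; nx.fwd = false; }
    out.push_back(std::make_pair(b, nx));
  }
}

#endif
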