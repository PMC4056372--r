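#include "dbg.h"
#include <deque>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// read index: every valid k-mer window of every read, sorted by canonical
// word, so marker anchoring is a binary search
// ---------------------------------------------------------------------------

struct Entry {
  uint64_t key;
  int32_t read;
  int32_t off;
  uint8_t fwd;  // 1 when the window word equals its canonical form
};

struct ReadSet {
  int k;
  bool paired;  // mate of read i is read i^1 (interleaved storage)
  std::vector<std::string> seqs;
  std::vector<Entry> idx;

  std::pair<size_t, size_t> range(uint64_t key) const {
    Entry probe; probe.key = key;
    auto lo = std::lower_bound(idx.begin(), idx.end(), probe,
        [](const Entry& a, const Entry& b) { return a.key < b.key; });
    auto hi = std::upper_bound(lo, idx.end(), probe,
        [](const Entry& a, const Entry& b) { return a.key < b.key; });
    return std::make_pair((size_t)(lo - idx.begin()), (size_t)(hi - idx.begin()));
  }
};

// [[Rcpp::export]]
SEXP cpp_readset_build(CharacterVector reads, int k, bool paired) {
  ReadSet* rs = new ReadSet();
  rs->k = k; rs->paired = paired;
  rs->seqs.reserve((size_t)reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = CharacterVector::is_na(reads[i]) ? std::string() : as<std::string>(reads[i]);
    std::transform(s.begin(), s.end(), s.begin(), ::toupper);
    rs->seqs.push_back(s);
  }
  uint64_t mk = kmer_mask(k);
  uint64_t hi = 2ULL * (uint64_t)(k - 1);
  for (size_t r = 0; r < rs->seqs.size(); ++r) {
    const std::string& s = rs->seqs[r];
    if ((long)s.size() < k) continue;
    uint64_t w = 0, rc = 0; int valid = 0;
    for (long j = 0; j < (long)s.size(); ++j) {
      int b = base_code(s[(size_t)j]);
      if (b < 0) { valid = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mk;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
      if (++valid < k) continue;
      Entry e;
      bool fwd = w <= rc;
      e.key = fwd ? w : rc;
      e.read = (int32_t)r;
      e.off = (int32_t)(j - k + 1);
      e.fwd = fwd ? 1 : 0;
      rs->idx.push_back(e);
    }
  }
  std::sort(rs->idx.begin(), rs->idx.end(), [](const Entry& a, const Entry& b) {
    if (a.key != b.key) return a.key < b.key;
    if (a.read != b.read) return a.read < b.read;
    return a.off < b.off;
  });
  XPtr<ReadSet> p(rs, true);
  return p;
}

// ---------------------------------------------------------------------------
// seeds: maximal paths whose internal vertices have exactly one present
// predecessor and successor (presence = coverage >= cov_present)
// ---------------------------------------------------------------------------

static void present_successors(const DBG& g, const Oriented& o, int cov_present,
                               std::vector<std::pair<int, Oriented>>& out) {
  const Vertex* v = g.find(o.km);
  out.clear();
  if (!v || v->cov < cov_present) return;
  std::vector<std::pair<int, Oriented>> succ;
  walk_successors(g, o, *v, succ);
  for (auto& s : succ) {
    const Vertex* t = g.find(s.second.km);
    if (t && t->cov >= cov_present) out.push_back(s);
  }
}

static std::string walk_sequence(const DBG& g, const std::vector<Oriented>& walk) {
  std::string s = decode_kmer(walk_word(g, walk[0]), g.k);
  for (size_t i = 1; i < walk.size(); ++i)
    s.push_back(code_base((int)(walk_word(g, walk[i]) & 3ULL)));
  return s;
}

// extend a unitig walk forward while the continuation is unambiguous on
// both sides; `visited` guards vertex-disjointness across seeds
static void unitig_forward(const DBG& g, std::vector<Oriented>& walk,
                           std::unordered_set<uint64_t>& inwalk,
                           const std::unordered_set<uint64_t>& visited,
                           int cov_present) {
  std::vector<std::pair<int, Oriented>> fwd, bwd;
  for (;;) {
    present_successors(g, walk.back(), cov_present, fwd);
    if (fwd.size() != 1) return;
    Oriented nx = fwd[0].second;
    if (inwalk.count(nx.km) || visited.count(nx.km)) return;
    // the continuation vertex must have exactly one present predecessor
    Oriented back_nx; back_nx.km = nx.km; back_nx.fwd = !nx.fwd;
    present_successors(g, back_nx, cov_present, bwd);
    if (bwd.size() != 1) return;
    walk.push_back(nx);
    inwalk.insert(nx.km);
  }
}

// [[Rcpp::export]]
CharacterVector cpp_find_seeds(SEXP ptr, int cov_present, int min_seed_nt) {
  XPtr<DBG> g(ptr);
  std::vector<uint64_t> pres;
  for (const auto& m : g->shards)
    for (const auto& kv : m)
      if (kv.second.cov >= cov_present) pres.push_back(kv.first);
  std::sort(pres.begin(), pres.end());
  std::unordered_set<uint64_t> visited;
  std::vector<std::string> seeds;
  for (uint64_t v : pres) {
    if (visited.count(v)) continue;
    std::vector<Oriented> walk;
    Oriented o; o.km = v; o.fwd = true;
    walk.push_back(o);
    std::unordered_set<uint64_t> inwalk;
    inwalk.insert(v);
    unitig_forward(*g, walk, inwalk, visited, cov_present);
    // extend the other way: flip, extend forward, flip back
    std::reverse(walk.begin(), walk.end());
    for (auto& w : walk) w.fwd = !w.fwd;
    unitig_forward(*g, walk, inwalk, visited, cov_present);
    std::reverse(walk.begin(), walk.end());
    for (auto& w : walk) w.fwd = !w.fwd;
    for (auto& w : walk) visited.insert(w.km);
    std::string s = walk_sequence(*g, walk);
    if ((int)s.size() < min_seed_nt) continue;
    std::string rc = revcomp_str(s);
    seeds.push_back(std::min(s, rc));
  }
  std::sort(seeds.begin(), seeds.end());
  return wrap(seeds);
}

// coverage multiset of a path given by its sequence; mode ties break low
static void path_coverages(const DBG& g, const std::string& seq, std::vector<int>& cov) {
  cov.clear();
  int k = g.k;
  uint64_t mk = kmer_mask(k);
  uint64_t hi = 2ULL * (uint64_t)(k - 1);
  uint64_t w = 0, rc = 0; int valid = 0;
  for (long j = 0; j < (long)seq.size(); ++j) {
    int b = base_code(seq[(size_t)j]);
    if (b < 0) stop("path sequence contains a non-ACGT character");
    w = ((w << 2) | (uint64_t)b) & mk;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
    if (++valid < k) continue;
    const Vertex* v = g.find(std::min(w, rc));
    cov.push_back(v ? (int)v->cov : 0);
  }
}

static void mode_min(const std::vector<int>& cov, int& mode, int& mn) {
  std::map<int, int> h;
  mn = cov.empty() ? 0 : cov[0];
  for (int c : cov) { h[c]++; if (c < mn) mn = c; }
  mode = 0; int best = 0;
  for (auto& kv : h)
    if (kv.second > best) { best = kv.second; mode = kv.first; }
}

// [[Rcpp::export]]
List cpp_seed_stats(SEXP ptr, std::string seq) {
  XPtr<DBG> g(ptr);
  std::transform(seq.begin(), seq.end(), seq.begin(), ::toupper);
  std::vector<int> cov;
  path_coverages(*g, seq, cov);
  int mode, mn;
  mode_min(cov, mode, mn);
  return List::create(_["mode"] = mode, _["min"] = mn, _["coverages"] = wrap(cov));
}

// ---------------------------------------------------------------------------
// markers and extension
// ---------------------------------------------------------------------------

struct PathWalk {
  std::vector<Oriented> walk;
  std::string seq;
  std::unordered_set<uint64_t> inpath;
};

static bool seq_to_walk(const DBG& g, const std::string& seq, PathWalk& p) {
  p.walk.clear(); p.inpath.clear();
  p.seq = seq;
  int k = g.k;
  uint64_t mk = kmer_mask(k);
  uint64_t hi = 2ULL * (uint64_t)(k - 1);
  uint64_t w = 0, rc = 0; int valid = 0;
  for (long j = 0; j < (long)seq.size(); ++j) {
    int b = base_code(seq[(size_t)j]);
    if (b < 0) return false;
    w = ((w << 2) | (uint64_t)b) & mk;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
    if (++valid < k) continue;
    Oriented o;
    o.fwd = w <= rc;
    o.km = o.fwd ? w : rc;
    p.walk.push_back(o);
    p.inpath.insert(o.km);
  }
  return !p.walk.empty();
}

struct Marker {
  int32_t read;
  int64_t start;     // projected 0-based start of the read on the path
  uint8_t fwd;       // read direction equals walk direction
  int64_t path_off;  // k-mer index of the anchoring window
  int32_t read_off;  // window offset within the read
};

struct ExtendCfg {
  int cov_present;
  int min_cov;          // seed minimum coverage
  double repeat_cutoff; // repeat_mult * seed mode coverage
  int vote_min;
  double vote_ratio;
  double insert_mean;
  double insert_sd;
};

class MarkerMachine {
public:
  const DBG& g;
  const ReadSet& rs;
  std::vector<int32_t> stamp;
  int32_t epoch = 0;
  std::vector<Marker> markers;

  MarkerMachine(const DBG& g_, const ReadSet& rs_)
    : g(g_), rs(rs_), stamp(rs_.seqs.size(), -1) {}

  void reset() { ++epoch; markers.clear(); }

  bool kmer_eligible(uint64_t km, const ExtendCfg& cfg) const {
    const Vertex* v = g.find(km);
    if (!v) return false;
    return v->cov >= cfg.min_cov && (double)v->cov <= cfg.repeat_cutoff;
  }

  // anchor unanchored reads whose k-mer sits at path index j
  void anchor_at(const PathWalk& p, size_t j, const ExtendCfg& cfg) {
    const Oriented& o = p.walk[j];
    if (!kmer_eligible(o.km, cfg)) return;
    auto rg = rs.range(o.km);
    int k = g.k;
    for (size_t t = rg.first; t < rg.second; ++t) {
      const Entry& e = rs.idx[t];
      if (stamp[(size_t)e.read] == epoch) continue;
      int L = (int)rs.seqs[(size_t)e.read].size();
      Marker m;
      m.read = e.read;
      m.fwd = (e.fwd == (o.fwd ? 1 : 0)) ? 1 : 0;
      m.start = m.fwd ? (int64_t)j - e.off
                      : (int64_t)j - (L - k - e.off);
      m.path_off = (int64_t)j;
      m.read_off = e.off;
      markers.push_back(m);
      stamp[(size_t)e.read] = epoch;
    }
  }

  // seed anchoring under the read-order rule: each read is markered at its
  // first read k-mer lying on the seed and passing the coverage cutoffs
  void anchor_seed(const PathWalk& p, const ExtendCfg& cfg) {
    int k = g.k;
    std::unordered_map<int32_t, Marker> best;
    for (size_t j = 0; j < p.walk.size(); ++j) {
      const Oriented& o = p.walk[j];
      if (!kmer_eligible(o.km, cfg)) continue;
      auto rg = rs.range(o.km);
      for (size_t t = rg.first; t < rg.second; ++t) {
        const Entry& e = rs.idx[t];
        auto it = best.find(e.read);
        if (it != best.end() && it->second.read_off <= e.off) continue;
        int L = (int)rs.seqs[(size_t)e.read].size();
        Marker m;
        m.read = e.read;
        m.fwd = (e.fwd == (o.fwd ? 1 : 0)) ? 1 : 0;
        m.start = m.fwd ? (int64_t)j - e.off
                        : (int64_t)j - (L - k - e.off);
        m.path_off = (int64_t)j;
        m.read_off = e.off;
        best[e.read] = m;
      }
    }
    std::vector<int32_t> order;
    order.reserve(best.size());
    for (auto& kv : best) order.push_back(kv.first);
    std::sort(order.begin(), order.end());
    for (int32_t r : order) {
      markers.push_back(best[(size_t)0 + r]);
      stamp[(size_t)r] = epoch;
    }
  }
};

static char read_base_at(const ReadSet& rs, const Marker& m, int64_t q) {
  const std::string& s = rs.seqs[(size_t)m.read];
  int64_t pos = q - m.start;
  if (pos < 0 || pos >= (int64_t)s.size()) return 0;
  return m.fwd ? s[(size_t)pos] : comp_char(s[(size_t)(s.size() - 1 - pos)]);
}

static bool mate_has_kmer(const ReadSet& rs, int32_t mate, uint64_t canon, int k) {
  const std::string& s = rs.seqs[(size_t)mate];
  if ((long)s.size() < k) return false;
  uint64_t mk = kmer_mask(k);
  uint64_t hi = 2ULL * (uint64_t)(k - 1);
  uint64_t w = 0, rc = 0; int valid = 0;
  for (long j = 0; j < (long)s.size(); ++j) {
    int b = base_code(s[(size_t)j]);
    if (b < 0) { valid = 0; continue; }
    w = ((w << 2) | (uint64_t)b) & mk;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
    if (++valid >= k && std::min(w, rc) == canon) return true;
  }
  return false;
}

// decisive winner among candidate votes: a unique top with
// votes >= vote_min and votes >= vote_ratio * runner-up
static int decide(const std::vector<double>& votes, int vote_min, double vote_ratio) {
  int top = -1;
  double best = -1, runner = -1;
  for (size_t i = 0; i < votes.size(); ++i) {
    if (votes[i] > best) { runner = best; best = votes[i]; top = (int)i; }
    else if (votes[i] > runner) runner = votes[i];
  }
  int ties = 0;
  for (double v : votes) if (v == best) ++ties;
  if (ties > 1) return -1;
  if (best < (double)vote_min) return -1;
  if (best < vote_ratio * std::max(runner, 0.0)) return -1;
  return top;
}

// stop reasons
static const char* STOP_NO_SUCC = "no-successor";
static const char* STOP_AMBIG = "ambiguous";
static const char* STOP_CYCLE = "cycle";
static const char* STOP_CONFLICT = "conflict";

static std::string extend_right(const DBG& g, const ReadSet& rs, PathWalk& p,
                                MarkerMachine& mm, const ExtendCfg& cfg) {
  std::vector<std::pair<int, Oriented>> cand;
  for (;;) {
    present_successors(g, p.walk.back(), cfg.cov_present, cand);
    if (cand.empty()) return STOP_NO_SUCC;
    int chosen = 0;
    if (cand.size() > 1) {
      int64_t q = (int64_t)p.seq.size();  // decision position in nucleotides
      // prune markers whose read lies entirely behind the decision position
      size_t w = 0;
      for (size_t i = 0; i < mm.markers.size(); ++i) {
        const Marker& m = mm.markers[i];
        int64_t L = (int64_t)rs.seqs[(size_t)m.read].size();
        if (m.start + L > q) mm.markers[w++] = m;
      }
      mm.markers.resize(w);
      // (a) marker votes: reads laid along the path that cover the decision
      // position vote for the base they read out
      std::vector<double> mv(cand.size(), 0.0);
      double tally[4] = {0, 0, 0, 0};
      for (const Marker& m : mm.markers) {
        char rb = read_base_at(rs, m, q);
        int b = rb ? base_code(rb) : -1;
        if (b >= 0) tally[b] += 1;
      }
      for (size_t i = 0; i < cand.size(); ++i) mv[i] = tally[cand[i].first];
      int dm = decide(mv, cfg.vote_min, cfg.vote_ratio);
      // (b) mate votes: mates of forward on-path reads projected over the
      // decision position vote for candidates whose k-mer they contain
      int dp = -1;
      if (rs.paired) {
        std::vector<double> pv(cand.size(), 0.0);
        for (const Marker& m : mm.markers) {
          if (!m.fwd) continue;
          int32_t mate = m.read ^ 1;
          if (mate < 0 || mate >= (int32_t)rs.seqs.size()) continue;
          int64_t Lm = (int64_t)rs.seqs[(size_t)mate].size();
          int64_t d = q - m.start;
          if ((double)d < cfg.insert_mean - 3.0 * cfg.insert_sd - (double)Lm) continue;
          if ((double)d >= cfg.insert_mean + 3.0 * cfg.insert_sd) continue;
          for (size_t i = 0; i < cand.size(); ++i)
            if (mate_has_kmer(rs, mate, cand[i].second.km, g.k)) pv[i] += 1;
        }
        dp = decide(pv, cfg.vote_min, cfg.vote_ratio);
      }
      if (dm >= 0 && dp >= 0 && dm != dp) return STOP_CONFLICT;
      chosen = dm >= 0 ? dm : dp;
      if (chosen < 0) return STOP_AMBIG;
    }
    const Oriented& nx = cand[(size_t)chosen].second;
    if (p.inpath.count(nx.km)) return STOP_CYCLE;
    p.walk.push_back(nx);
    p.inpath.insert(nx.km);
    p.seq.push_back(code_base(cand[(size_t)chosen].first));
    mm.anchor_at(p, p.walk.size() - 1, cfg);
  }
}

static void flip_path(PathWalk& p) {
  std::reverse(p.walk.begin(), p.walk.end());
  for (auto& o : p.walk) o.fwd = !o.fwd;
  p.seq = revcomp_str(p.seq);
}

// [[Rcpp::export]]
DataFrame cpp_select_markers(SEXP gptr, SEXP rsptr, std::string seed,
                             int min_cov, double repeat_cutoff, int cov_present) {
  XPtr<DBG> g(gptr);
  XPtr<ReadSet> rs(rsptr);
  std::transform(seed.begin(), seed.end(), seed.begin(), ::toupper);
  PathWalk p;
  if (!seq_to_walk(*g, seed, p)) stop("seed sequence is shorter than k or invalid");
  ExtendCfg cfg;
  cfg.cov_present = cov_present; cfg.min_cov = min_cov;
  cfg.repeat_cutoff = repeat_cutoff;
  cfg.vote_min = 2; cfg.vote_ratio = 2; cfg.insert_mean = 0; cfg.insert_sd = 0;
  MarkerMachine mm(*g, *rs);
  mm.reset();
  mm.anchor_seed(p, cfg);
  R_xlen_t n = (R_xlen_t)mm.markers.size();
  IntegerVector read(n), path_off(n), read_off(n);
  NumericVector start(n);
  CharacterVector strand(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const Marker& m = mm.markers[(size_t)i];
    read[i] = m.read + 1;
    path_off[i] = (int)m.path_off;
    read_off[i] = m.read_off;
    start[i] = (double)m.start;
    strand[i] = m.fwd ? "+" : "-";
  }
  return DataFrame::create(_["read"] = read, _["path_offset"] = path_off,
                           _["read_offset"] = read_off, _["strand"] = strand,
                           _["proj_start"] = start, _["stringsAsFactors"] = false);
}

// outer fragment distances for pairs with both mates markered on one seed
// [[Rcpp::export]]
NumericVector cpp_insert_observations(SEXP gptr, SEXP rsptr, CharacterVector seeds,
                                      double repeat_mult, int cov_present) {
  XPtr<DBG> g(gptr);
  XPtr<ReadSet> rs(rsptr);
  if (!rs->paired) return NumericVector(0);
  std::vector<double> obs;
  MarkerMachine mm(*g, *rs);
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    std::string seed = as<std::string>(seeds[s]);
    std::transform(seed.begin(), seed.end(), seed.begin(), ::toupper);
    PathWalk p;
    if (!seq_to_walk(*g, seed, p)) continue;
    std::vector<int> cov; int mode, mn;
    path_coverages(*g, p.seq, cov);
    mode_min(cov, mode, mn);
    ExtendCfg cfg;
    cfg.cov_present = cov_present; cfg.min_cov = mn;
    cfg.repeat_cutoff = repeat_mult * (double)mode;
    cfg.vote_min = 2; cfg.vote_ratio = 2; cfg.insert_mean = 0; cfg.insert_sd = 0;
    mm.reset();
    mm.anchor_seed(p, cfg);
    std::unordered_map<int32_t, const Marker*> by_read;
    for (const Marker& m : mm.markers) by_read[m.read] = &m;
    for (const Marker& m : mm.markers) {
      if (m.read % 2 != 0) continue;  // visit each pair once
      auto it = by_read.find(m.read ^ 1);
      if (it == by_read.end()) continue;
      const Marker& m2 = *it->second;
      if (m.fwd == m2.fwd) continue;  // require opposite orientations
      int64_t L1 = (int64_t)rs->seqs[(size_t)m.read].size();
      int64_t L2 = (int64_t)rs->seqs[(size_t)m2.read].size();
      int64_t lo = std::min(m.start, m2.start);
      int64_t hi = std::max(m.start + L1, m2.start + L2);
      obs.push_back((double)(hi - lo));
    }
  }
  return wrap(obs);
}

// [[Rcpp::export]]
List cpp_extend_seed(SEXP gptr, SEXP rsptr, std::string seed, int cov_present,
                     double repeat_mult, int vote_min, double vote_ratio,
                     double insert_mean, double insert_sd) {
  XPtr<DBG> g(gptr);
  XPtr<ReadSet> rs(rsptr);
  std::transform(seed.begin(), seed.end(), seed.begin(), ::toupper);
  PathWalk p;
  if (!seq_to_walk(*g, seed, p)) stop("seed sequence is shorter than k or invalid");
  std::vector<int> cov; int mode, mn;
  path_coverages(*g, p.seq, cov);
  mode_min(cov, mode, mn);
  ExtendCfg cfg;
  cfg.cov_present = cov_present; cfg.min_cov = mn;
  cfg.repeat_cutoff = repeat_mult * (double)mode;
  cfg.vote_min = vote_min; cfg.vote_ratio = vote_ratio;
  cfg.insert_mean = insert_mean; cfg.insert_sd = insert_sd;
  MarkerMachine mm(*g, *rs);
  mm.reset();
  mm.anchor_seed(p, cfg);
  std::string stop_r = extend_right(*g, *rs, p, mm, cfg);
  flip_path(p);
  mm.reset();
  mm.anchor_seed(p, cfg);
  std::string stop_l = extend_right(*g, *rs, p, mm, cfg);
  // current orientation: left end carries stop_r, right end stop_l
  std::string seq = p.seq;
  std::string rc = revcomp_str(seq);
  std::string left = stop_r, right = stop_l;
  if (rc < seq) { seq = rc; std::swap(left, right); }
  return List::create(_["sequence"] = seq, _["stop_left"] = left,
                      _["stop_right"] = right);
}

// full extension pipeline over sorted seeds with claimed-vertex skipping and
// duplicate/containment removal
// [[Rcpp::export]]
List cpp_extend_all(SEXP gptr, SEXP rsptr, CharacterVector seeds, int cov_present,
                    double repeat_mult, int vote_min, double vote_ratio,
                    double insert_mean, double insert_sd) {
  XPtr<DBG> g(gptr);
  XPtr<ReadSet> rs(rsptr);
  std::unordered_set<uint64_t> claimed;
  std::vector<std::string> out_seq, out_l, out_r;
  std::vector<int> out_seed;
  int n_skipped = 0;
  MarkerMachine mm(*g, *rs);
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    std::string seed = as<std::string>(seeds[s]);
    std::transform(seed.begin(), seed.end(), seed.begin(), ::toupper);
    PathWalk p;
    if (!seq_to_walk(*g, seed, p)) continue;
    bool fresh = false;
    for (const Oriented& o : p.walk)
      if (!claimed.count(o.km)) { fresh = true; break; }
    if (!fresh) { ++n_skipped; continue; }
    std::vector<int> cov; int mode, mn;
    path_coverages(*g, p.seq, cov);
    mode_min(cov, mode, mn);
    ExtendCfg cfg;
    cfg.cov_present = cov_present; cfg.min_cov = mn;
    cfg.repeat_cutoff = repeat_mult * (double)mode;
    cfg.vote_min = vote_min; cfg.vote_ratio = vote_ratio;
    cfg.insert_mean = insert_mean; cfg.insert_sd = insert_sd;
    mm.reset();
    mm.anchor_seed(p, cfg);
    std::string stop_r = extend_right(*g, *rs, p, mm, cfg);
    flip_path(p);
    mm.reset();
    mm.anchor_seed(p, cfg);
    std::string stop_l = extend_right(*g, *rs, p, mm, cfg);
    for (const Oriented& o : p.walk) claimed.insert(o.km);
    std::string seq = p.seq;
    std::string rc = revcomp_str(seq);
    std::string left = stop_r, right = stop_l;
    if (rc < seq) { seq = rc; std::swap(left, right); }
    out_seq.push_back(seq);
    out_l.push_back(left);
    out_r.push_back(right);
    out_seed.push_back((int)s + 1);
  }
  // exact duplicates, then walk containment (all of a contig's k-mers owned
  // by one longer contig)
  std::vector<size_t> order(out_seq.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](size_t a, size_t b) {
    if (out_seq[a].size() != out_seq[b].size()) return out_seq[a].size() > out_seq[b].size();
    return out_seq[a] < out_seq[b];
  });
  std::unordered_set<std::string> seen;
  std::unordered_map<uint64_t, int> owner;
  std::vector<bool> keep(out_seq.size(), false);
  int n_dropped = 0;
  for (size_t oi = 0; oi < order.size(); ++oi) {
    size_t i = order[oi];
    if (seen.count(out_seq[i])) { ++n_dropped; continue; }
    PathWalk p;
    seq_to_walk(*g, out_seq[i], p);
    bool contained = !p.walk.empty();
    int own = -2;
    for (const Oriented& o : p.walk) {
      auto it = owner.find(o.km);
      if (it == owner.end()) { contained = false; break; }
      if (own == -2) own = it->second;
      else if (own != it->second) { contained = false; break; }
    }
    if (contained) { ++n_dropped; continue; }
    seen.insert(out_seq[i]);
    keep[i] = true;
    for (const Oriented& o : p.walk)
      if (!owner.count(o.km)) owner[o.km] = (int)i;
  }
  std::vector<std::string> f_seq, f_l, f_r;
  std::vector<int> f_seed;
  for (size_t i = 0; i < out_seq.size(); ++i) {
    if (!keep[i]) continue;
    f_seq.push_back(out_seq[i]);
    f_l.push_back(out_l[i]);
    f_r.push_back(out_r[i]);
    f_seed.push_back(out_seed[i]);
  }
  DataFrame df = DataFrame::create(_["sequence"] = f_seq, _["stop_left"] = f_l,
                                   _["stop_right"] = f_r, _["seed"] = f_seed,
                                   _["stringsAsFactors"] = false);
  return List::create(_["contigs"] = df, _["n_seeds"] = (int)seeds.size(),
                      _["n_skipped_claimed"] = n_skipped,
                      _["n_dropped_contained"] = n_dropped);
}

// anchor each read onto a contig set at its first unambiguously placed
// k-mer (used for scaffolding links)
// [[Rcpp::export]]
DataFrame cpp_anchor_reads(CharacterVector contigs, SEXP rsptr) {
  XPtr<ReadSet> rs(rsptr);
  int k = rs->k;
  struct Pos { int32_t contig; int32_t pos; uint8_t fwd; };
  std::unordered_map<uint64_t, Pos> map;
  std::unordered_set<uint64_t> ambig;
  uint64_t mk = kmer_mask(k);
  uint64_t hi = 2ULL * (uint64_t)(k - 1);
  for (R_xlen_t c = 0; c < contigs.size(); ++c) {
    std::string s = as<std::string>(contigs[c]);
    std::transform(s.begin(), s.end(), s.begin(), ::toupper);
    if ((long)s.size() < k) continue;
    uint64_t w = 0, rc = 0; int valid = 0;
    for (long j = 0; j < (long)s.size(); ++j) {
      int b = base_code(s[(size_t)j]);
      if (b < 0) { valid = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mk;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
      if (++valid < k) continue;
      uint64_t can = std::min(w, rc);
      if (ambig.count(can)) continue;
      auto it = map.find(can);
      if (it != map.end()) { map.erase(it); ambig.insert(can); continue; }
      Pos p; p.contig = (int32_t)c; p.pos = (int32_t)(j - k + 1);
      p.fwd = (w <= rc) ? 1 : 0;
      map[can] = p;
    }
  }
  std::vector<int> read, contig, rlen; std::vector<double> start;
  std::vector<std::string> strand;
  for (size_t r = 0; r < rs->seqs.size(); ++r) {
    const std::string& s = rs->seqs[r];
    if ((long)s.size() < k) continue;
    uint64_t w = 0, rc = 0; int valid = 0;
    for (long j = 0; j < (long)s.size(); ++j) {
      int b = base_code(s[j]);
      if (b < 0) { valid = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mk;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
      if (++valid < k) continue;
      uint64_t can = std::min(w, rc);
      auto it = map.find(can);
      if (it == map.end()) continue;
      const Pos& p = it->second;
      bool rfwd = ((w <= rc) ? 1 : 0) == p.fwd;
      int L = (int)s.size();
      long off = j - k + 1;
      double st = rfwd ? (double)p.pos - off : (double)p.pos - (L - k - off);
      read.push_back((int)r + 1);
      contig.push_back((int)p.contig + 1);
      start.push_back(st);
      strand.push_back(rfwd ? "+" : "-");
      rlen.push_back(L);
      break;
    }
  }
  return DataFrame::create(_["read"] = read, _["contig"] = contig,
                           _["start"] = start, _["strand"] = strand,
                           _["read_len"] = rlen, _["stringsAsFactors"] = false);
}
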