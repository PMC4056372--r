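#include "dbg.h"
using namespace Rcpp;

static void ingest_sequence(DBG& g, const std::string& seq) {
  int k = g.k;
  long n = (long)seq.size();
  if (n < k) return;
  uint64_t mk = kmer_mask(k);
  uint64_t hi = 2ULL * (uint64_t)(k - 1);
  uint64_t w = 0, rc = 0;
  int valid = 0;
  bool have_prev = false;
  uint64_t prev_can = 0;
  bool prev_fwd = true;
  int prev_first = 0;  // base code of the first base of the previous window
  for (long i = 0; i < n; ++i) {
    int b = base_code(seq[(size_t)i]);
    if (b < 0) { valid = 0; have_prev = false; continue; }
    w = ((w << 2) | (uint64_t)b) & mk;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
    if (++valid < k) { continue; }
    bool fwd = w <= rc;
    uint64_t can = fwd ? w : rc;
    Vertex& v = g.at_insert(can);
    if (v.cov == 65535) g.saturated++; else v.cov++;
    g.windows++;
    if (have_prev) {
      // edge prev -> current, with b the appended base and prev_first the
      // base dropped from the previous window
      Vertex& pv = *g.find(prev_can);
      if (prev_fwd) pv.out |= (uint8_t)(1u << b);
      else pv.in |= (uint8_t)(1u << (3 - b));
      if (fwd) v.in |= (uint8_t)(1u << prev_first);
      else v.out |= (uint8_t)(1u << (3 - prev_first));
    }
    prev_can = can; prev_fwd = fwd; have_prev = true;
    prev_first = (int)((w >> hi) & 3ULL);
  }
}

// [[Rcpp::export]]
SEXP cpp_dbg_build(CharacterVector reads, int k, int shards) {
  DBG* g = new DBG(k, shards);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    if (CharacterVector::is_na(reads[i])) { g->skipped++; continue; }
    std::string s = as<std::string>(reads[i]);
    std::transform(s.begin(), s.end(), s.begin(), ::toupper);
    if ((long)s.size() < k) { g->skipped++; continue; }
    ingest_sequence(*g, s);
  }
  XPtr<DBG> p(g, true);
  return p;
}

// [[Rcpp::export]]
List cpp_dbg_stats(SEXP ptr) {
  XPtr<DBG> g(ptr);
  double cov_sum = 0;
  for (const auto& m : g->shards)
    for (const auto& kv : m) cov_sum += kv.second.cov;
  return List::create(_["n_vertices"] = (double)g->size(),
                      _["k"] = g->k, _["shards"] = g->S,
                      _["windows"] = (double)g->windows,
                      _["coverage_sum"] = cov_sum,
                      _["saturated"] = (double)g->saturated,
                      _["skipped_records"] = (double)g->skipped);
}

// [[Rcpp::export]]
DataFrame cpp_dbg_histogram(SEXP ptr) {
  XPtr<DBG> g(ptr);
  std::map<int, double> h;
  for (const auto& m : g->shards)
    for (const auto& kv : m) h[kv.second.cov] += 1.0;
  std::vector<int> cov; std::vector<double> n;
  for (auto& kv : h) { cov.push_back(kv.first); n.push_back(kv.second); }
  return DataFrame::create(_["coverage"] = cov, _["n"] = n);
}

static uint64_t parse_canonical(const DBG& g, const std::string& word) {
  if ((int)word.size() != g.k)
    stop("k-mer must have length k = %d", g.k);
  std::string w = word;
  std::transform(w.begin(), w.end(), w.begin(), ::toupper);
  uint64_t v;
  long bad = encode_kmer(w, v);
  if (bad >= 0) stop("non-ACGT character at position %d", (int)bad + 1);
  uint64_t rc = revcomp_bits(v, g.k);
  return std::min(v, rc);
}

// [[Rcpp::export]]
DataFrame cpp_dbg_vertices(SEXP ptr, CharacterVector kmers) {
  XPtr<DBG> g(ptr);
  R_xlen_t n = kmers.size();
  CharacterVector can(n);
  LogicalVector present(n);
  IntegerVector cov(n), outm(n), inm(n);
  List colors(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t c = parse_canonical(*g, as<std::string>(kmers[i]));
    can[i] = decode_kmer(c, g->k);
    const Vertex* v = g->find(c);
    if (!v) {
      present[i] = false; cov[i] = 0; outm[i] = 0; inm[i] = 0;
      colors[i] = IntegerVector(0);
    } else {
      present[i] = true; cov[i] = v->cov; outm[i] = v->out; inm[i] = v->in;
      colors[i] = wrap(g->color_sets[(size_t)v->cs]);
    }
  }
  DataFrame out = DataFrame::create(_["kmer"] = can, _["present"] = present,
                                    _["coverage"] = cov, _["out_mask"] = outm,
                                    _["in_mask"] = inm, _["stringsAsFactors"] = false);
  out["colors"] = colors;
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_dbg_neighbors(SEXP ptr, std::string kmer, bool forward) {
  XPtr<DBG> g(ptr);
  uint64_t c = parse_canonical(*g, kmer);
  const Vertex* v = g->find(c);
  if (!v) stop("k-mer not present in graph");
  Oriented o; o.km = c; o.fwd = forward;
  std::vector<std::pair<int, Oriented>> succ;
  walk_successors(*g, o, *v, succ);
  std::vector<std::string> base, nk;
  for (auto& s : succ) {
    if (!g->find(s.second.km)) continue;  // edge marked but vertex never stored: impossible by construction
    base.push_back(std::string(1, code_base(s.first)));
    nk.push_back(decode_kmer(s.second.km, g->k));
  }
  return DataFrame::create(_["base"] = base, _["kmer"] = nk,
                           _["stringsAsFactors"] = false);
}

// flat dump sorted by packed canonical word; byte-identical across shard
// counts and read orderings
// [[Rcpp::export]]
DataFrame cpp_dbg_serialize(SEXP ptr) {
  XPtr<DBG> g(ptr);
  std::vector<uint64_t> keys;
  keys.reserve(g->size());
  for (const auto& m : g->shards)
    for (const auto& kv : m) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  R_xlen_t n = (R_xlen_t)keys.size();
  CharacterVector km(n), cols(n);
  IntegerVector cov(n), outm(n), inm(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const Vertex* v = g->find(keys[(size_t)i]);
    km[i] = decode_kmer(keys[(size_t)i], g->k);
    cov[i] = v->cov; outm[i] = v->out; inm[i] = v->in;
    const std::vector<int>& cs = g->color_sets[(size_t)v->cs];
    std::string s;
    for (size_t j = 0; j < cs.size(); ++j) {
      if (j) s += ",";
      s += std::to_string(cs[j]);
    }
    cols[i] = s;
  }
  return DataFrame::create(_["kmer"] = km, _["coverage"] = cov,
                           _["out_mask"] = outm, _["in_mask"] = inm,
                           _["colors"] = cols, _["stringsAsFactors"] = false);
}

// Color every pre-existing vertex whose canonical k-mer occurs in the
// reference; topology and coverage untouched. Returns matched / total
// windows per reference.
// [[Rcpp::export]]
DataFrame cpp_dbg_color(SEXP ptr, CharacterVector seqs, IntegerVector color_ids) {
  XPtr<DBG> g(ptr);
  int k = g->k;
  R_xlen_t n = seqs.size();
  NumericVector matched(n), total(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::transform(s.begin(), s.end(), s.begin(), ::toupper);
    int color = color_ids[i];
    long len = (long)s.size();
    double m = 0, t = 0;
    if (len >= k) {
      uint64_t mk = kmer_mask(k), w = 0, rc = 0;
      uint64_t hi = 2ULL * (uint64_t)(k - 1);
      int valid = 0;
      for (long j = 0; j < len; ++j) {
        int b = base_code(s[(size_t)j]);
        if (b < 0) { valid = 0; continue; }
        w = ((w << 2) | (uint64_t)b) & mk;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
        if (++valid < k) continue;
        t += 1;
        Vertex* v = g->find(std::min(w, rc));
        if (v) { m += 1; v->cs = g->intern_with(v->cs, color); }
      }
    }
    matched[i] = m; total[i] = t;
  }
  return DataFrame::create(_["matched"] = matched, _["total"] = total);
}

// [[Rcpp::export]]
int cpp_dbg_n_color_sets(SEXP ptr) {
  XPtr<DBG> g(ptr);
  return (int)g->color_sets.size();
}

// Aggregate colored coverage within one namespace (= the set of allowed
// color ids). Returns, per color: count of distinct graph k-mers carrying
// it, and the coverage histogram over k-mers uniquely colored by it; plus
// the distinct restricted color sets with their total coverage and k-mer
// counts, and the namespace-wide coverage total.
// [[Rcpp::export]]
List cpp_dbg_color_summary(SEXP ptr, IntegerVector allowed) {
  XPtr<DBG> g(ptr);
  std::unordered_set<int> ns(allowed.begin(), allowed.end());
  size_t ncs = g->color_sets.size();
  // restrict each interned set to the namespace once
  std::vector<std::vector<int>> restr(ncs);
  for (size_t i = 0; i < ncs; ++i)
    for (int c : g->color_sets[i])
      if (ns.count(c)) restr[i].push_back(c);

  std::unordered_map<int, double> matched;                 // color -> distinct kmers
  std::map<std::pair<int, int>, double> unique_hist;       // (color, cov) -> kmers
  std::vector<double> set_cov(ncs, 0.0), set_n(ncs, 0.0);  // by interned id
  double total_cov = 0;
  for (const auto& m : g->shards) {
    for (const auto& kv : m) {
      const Vertex& v = kv.second;
      const std::vector<int>& rs = restr[(size_t)v.cs];
      if (rs.empty()) continue;
      total_cov += v.cov;
      set_cov[(size_t)v.cs] += v.cov;
      set_n[(size_t)v.cs] += 1;
      for (int c : rs) matched[c] += 1;
      if (rs.size() == 1) unique_hist[std::make_pair(rs[0], (int)v.cov)] += 1;
    }
  }
  std::vector<int> mc; std::vector<double> mn;
  for (auto& kv : matched) { mc.push_back(kv.first); mn.push_back(kv.second); }
  std::vector<int> uc, ucov; std::vector<double> un;
  for (auto& kv : unique_hist) {
    uc.push_back(kv.first.first); ucov.push_back(kv.first.second);
    un.push_back(kv.second);
  }
  // distinct restricted sets actually seen
  std::map<std::vector<int>, std::pair<double, double>> sets;
  for (size_t i = 0; i < ncs; ++i) {
    if (set_n[i] == 0) continue;
    auto& agg = sets[restr[i]];
    agg.first += set_cov[i];
    agg.second += set_n[i];
  }
  List set_members(sets.size());
  NumericVector scov(sets.size()), sn(sets.size());
  size_t i = 0;
  for (auto& kv : sets) {
    set_members[i] = wrap(kv.first);
    scov[i] = kv.second.first; sn[i] = kv.second.second;
    ++i;
  }
  return List::create(
      _["total_coverage"] = total_cov,
      _["matched"] = DataFrame::create(_["color"] = mc, _["n_kmers"] = mn),
      _["unique_hist"] = DataFrame::create(_["color"] = uc, _["coverage"] = ucov,
                                           _["n_kmers"] = un),
      _["sets"] = set_members, _["set_coverage"] = scov, _["set_kmers"] = sn);
}

// directional shared-nucleotide computation between two assemblies: a base
// of `a` is shared when covered by >=1 window whose canonical k-mer occurs
// anywhere in `b`
// [[Rcpp::export]]
NumericVector cpp_shared_nt(CharacterVector a, CharacterVector b, int k) {
  std::unordered_set<uint64_t> bset;
  uint64_t mk = kmer_mask(k);
  uint64_t hi = 2ULL * (uint64_t)(k - 1);
  for (R_xlen_t i = 0; i < b.size(); ++i) {
    std::string s = as<std::string>(b[i]);
    std::transform(s.begin(), s.end(), s.begin(), ::toupper);
    uint64_t w = 0, rc = 0; int valid = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      int bb = base_code(s[j]);
      if (bb < 0) { valid = 0; continue; }
      w = ((w << 2) | (uint64_t)bb) & mk;
      rc = (rc >> 2) | ((uint64_t)(3 - bb) << hi);
      if (++valid >= k) bset.insert(std::min(w, rc));
    }
  }
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string s = as<std::string>(a[i]);
    std::transform(s.begin(), s.end(), s.begin(), ::toupper);
    long n = (long)s.size();
    double shared = 0;
    long covered_until = 0;  // exclusive end of covered prefix
    uint64_t w = 0, rc = 0; int valid = 0;
    for (long j = 0; j < n; ++j) {
      int bb = base_code(s[(size_t)j]);
      if (bb < 0) { valid = 0; continue; }
      w = ((w << 2) | (uint64_t)bb) & mk;
      rc = (rc >> 2) | ((uint64_t)(3 - bb) << hi);
      if (++valid < k) continue;
      if (bset.count(std::min(w, rc))) {
        long start = j - k + 1;
        long lo = std::max(start, covered_until);
        shared += (double)(j + 1 - lo);
        covered_until = j + 1;
      }
    }
    out[i] = shared;
  }
  return out;
}
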