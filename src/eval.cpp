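#include "dbg.h"
using namespace Rcpp;

// Maximal exact matches >= k between query sequences and references, found
// as maximal runs of matching k-mer windows along a diagonal. Coordinates
// are 0-based half-open on the forward strand of both sequences.
// [[Rcpp::export]]
DataFrame cpp_exact_anchors(CharacterVector queries, CharacterVector refs, int k) {
  struct Hit { int32_t q; int32_t r; int8_t strand; int64_t diag; int64_t qpos; int64_t rpos; };
  // reference k-mer index
  struct RPos { int32_t r; int32_t pos; uint8_t fwd; };
  std::unordered_map<uint64_t, std::vector<RPos>> idx;
  uint64_t mk = kmer_mask(k);
  uint64_t hi = 2ULL * (uint64_t)(k - 1);
  for (R_xlen_t r = 0; r < refs.size(); ++r) {
    std::string s = as<std::string>(refs[r]);
    std::transform(s.begin(), s.end(), s.begin(), ::toupper);
    if ((long)s.size() < k) continue;
    uint64_t w = 0, rc = 0; int valid = 0;
    for (long j = 0; j < (long)s.size(); ++j) {
      int b = base_code(s[(size_t)j]);
      if (b < 0) { valid = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mk;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
      if (++valid < k) continue;
      RPos p; p.r = (int32_t)r; p.pos = (int32_t)(j - k + 1);
      p.fwd = (w <= rc) ? 1 : 0;
      idx[std::min(w, rc)].push_back(p);
    }
  }
  std::vector<Hit> hits;
  for (R_xlen_t q = 0; q < queries.size(); ++q) {
    std::string s = as<std::string>(queries[q]);
    std::transform(s.begin(), s.end(), s.begin(), ::toupper);
    if ((long)s.size() < k) continue;
    uint64_t w = 0, rc = 0; int valid = 0;
    for (long j = 0; j < (long)s.size(); ++j) {
      int b = base_code(s[(size_t)j]);
      if (b < 0) { valid = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mk;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
      if (++valid < k) continue;
      auto it = idx.find(std::min(w, rc));
      if (it == idx.end()) continue;
      uint8_t qfwd = (w <= rc) ? 1 : 0;
      long qpos = j - k + 1;
      for (const RPos& p : it->second) {
        Hit h;
        h.q = (int32_t)q; h.r = p.r;
        h.strand = (qfwd == p.fwd) ? 1 : -1;
        h.qpos = qpos; h.rpos = p.pos;
        h.diag = (h.strand > 0) ? ((int64_t)p.pos - qpos) : ((int64_t)p.pos + qpos);
        hits.push_back(h);
      }
    }
  }
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.q != b.q) return a.q < b.q;
    if (a.r != b.r) return a.r < b.r;
    if (a.strand != b.strand) return a.strand < b.strand;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qpos < b.qpos;
  });
  std::vector<int> oq, orf, ostr;
  std::vector<double> oqs, oqe, ors, ore, olen;
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i + 1;
    while (j < hits.size() && hits[j].q == hits[i].q && hits[j].r == hits[i].r &&
           hits[j].strand == hits[i].strand && hits[j].diag == hits[i].diag &&
           hits[j].qpos == hits[j - 1].qpos + 1)
      ++j;
    int64_t run = (int64_t)(j - i);
    int64_t len = run + k - 1;
    int64_t qs = hits[i].qpos;
    int64_t rs, re;
    if (hits[i].strand > 0) { rs = hits[i].rpos; re = rs + len; }
    else { rs = hits[j - 1].rpos; re = hits[i].rpos + k; }
    oq.push_back(hits[i].q + 1);
    orf.push_back(hits[i].r + 1);
    ostr.push_back(hits[i].strand);
    oqs.push_back((double)qs);
    oqe.push_back((double)(qs + len));
    ors.push_back((double)rs);
    ore.push_back((double)re);
    olen.push_back((double)len);
    i = j;
  }
  return DataFrame::create(_["query"] = oq, _["reference"] = orf,
                           _["strand"] = ostr, _["query_start"] = oqs,
                           _["query_end"] = oqe, _["ref_start"] = ors,
                           _["ref_end"] = ore, _["length"] = olen);
}

// per-read mismatch counts against the truth substrings (simulator
// calibration helper): a and b are equal-length string vectors
// [[Rcpp::export]]
NumericVector cpp_hamming(CharacterVector a, CharacterVector b) {
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string x = as<std::string>(a[i]);
    std::string y = as<std::string>(b[i]);
    size_t n = std::min(x.size(), y.size());
    double d = (double)(std::max(x.size(), y.size()) - n);
    for (size_t j = 0; j < n; ++j)
      if (::toupper(x[j]) != ::toupper(y[j])) d += 1;
    out[i] = d;
  }
  return out;
}
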