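#include "dbg.h"
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_canonical_kmer(std::string word) {
  int k = (int)word.size();
  std::transform(word.begin(), word.end(), word.begin(), ::toupper);
  uint64_t v;
  long bad = encode_kmer(word, v);
  if (bad >= 0)
    stop("non-ACGT character '%s' at position %d", std::string(1, word[(size_t)bad]).c_str(), (int)bad + 1);
  uint64_t rc = revcomp_bits(v, k);
  bool fwd = v <= rc;
  return List::create(_["kmer"] = decode_kmer(fwd ? v : rc, k),
                      _["strand"] = std::string(fwd ? "+" : "-"));
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::transform(s.begin(), s.end(), s.begin(), ::toupper);
  return revcomp_str(s);
}

// one row per window of length k containing only A,C,G,T; other windows skipped
// [[Rcpp::export]]
DataFrame cpp_extract_kmers(std::string seq, int k) {
  std::transform(seq.begin(), seq.end(), seq.begin(), ::toupper);
  std::vector<std::string> kmers;
  std::vector<std::string> strands;
  std::vector<int> offsets;
  long n = (long)seq.size();
  if (n >= k) {
    uint64_t mk = kmer_mask(k);
    uint64_t w = 0, rc = 0;
    int valid = 0;  // length of current run of ACGT ending at i
    uint64_t hi = 2ULL * (uint64_t)(k - 1);
    for (long i = 0; i < n; ++i) {
      int b = base_code(seq[(size_t)i]);
      if (b < 0) { valid = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mk;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << hi);
      if (++valid >= k) {
        bool fwd = w <= rc;
        kmers.push_back(decode_kmer(fwd ? w : rc, k));
        strands.push_back(fwd ? "+" : "-");
        offsets.push_back((int)(i - k + 1));
      }
    }
  }
  return DataFrame::create(_["kmer"] = kmers, _["strand"] = strands,
                           _["offset"] = offsets, _["stringsAsFactors"] = false);
}
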