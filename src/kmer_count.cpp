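#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else breaks the window.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Count canonical k-mers (lexicographic min of k-mer and reverse
// complement under A<C<G<T, which the 2-bit code preserves) over all
// ACGT-only windows of the input strings. Returns the multiplicity
// histogram as a two-column integer matrix (multiplicity, n_kmers).
// [[Rcpp::export(name = ".kmer_spectrum_cpp")]]
IntegerMatrix kmer_spectrum_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift_rc = 2 * (k - 1);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (const char* p = str; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
      }
    }
  }

  std::unordered_map<uint32_t, uint32_t> hist;
  for (const auto& kv : counts) ++hist[kv.second];
  IntegerMatrix out(hist.size(), 2);
  R_xlen_t i = 0;
  for (const auto& kv : hist) {
    out(i, 0) = (int)kv.first;
    out(i, 1) = (int)kv.second;
    ++i;
  }
  return out;
}

// Single-strand k-mer counts (no canonicalization) for arbitrary k,
// returned as parallel vectors of k-mer string and count.
// [[Rcpp::export(name = ".strand_kmer_counts_cpp")]]
List strand_kmer_counts_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0;
    int valid = 0;
    for (const char* p = str; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      if (++valid >= k) ++counts[fwd];
    }
  }

  const char bases[] = {'A', 'C', 'G', 'T'};
  CharacterVector kmers(counts.size());
  IntegerVector n(counts.size());
  R_xlen_t i = 0;
  std::string buf(k, 'A');
  for (const auto& kv : counts) {
    uint64_t code = kv.first;
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    kmers[i] = buf;
    n[i] = (int)kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmers, _["count"] = n);
}
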