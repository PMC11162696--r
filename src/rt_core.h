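#ifndef RT_CORE_H
#define RT_CORE_H

#include <cstdint>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>

namespace rt {

// ---- bijective avalanche hash (multiply-xorshift finalizer) ----

// multiplicative inverse of an odd 64-bit constant (Newton iteration)
inline uint64_t mulinv64(uint64_t a) {
  uint64_t x = a;
  for (int i = 0; i < 5; ++i) x *= 2 - a * x;
  return x;
}

inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

inline uint64_t inv_xorshift(uint64_t y, int s) {
  uint64_t x = y;
  for (int i = 0; i < 7; ++i) x = y ^ (x >> s);
  return x;
}

inline uint64_t unmix64(uint64_t y) {
  static const uint64_t inv1 = mulinv64(0x94d049bb133111ebULL);
  static const uint64_t inv0 = mulinv64(0xbf58476d1ce4e5b9ULL);
  uint64_t x = inv_xorshift(y, 31);
  x *= inv1;
  x = inv_xorshift(x, 27);
  x *= inv0;
  x = inv_xorshift(x, 30);
  return x;
}

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'a': return 't';
    case 'C': return 'G'; case 'c': return 'g';
    case 'G': return 'C'; case 'g': return 'c';
    case 'T': return 'A'; case 't': return 'a';
    default:  return 'N';
  }
}

inline std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

std::string hash_hex(uint64_t h);
bool hex_to_u64(const std::string& s, uint64_t& out);

// ---- sketching ----

struct Mmz {
  uint64_t hash;
  int32_t off;   // 0-based offset of the k-mer in the sequence
};

// per-position k-mer hashes; valid[i] == 0 when the k-mer at i contains an
// ambiguous base
void kmer_hashes(const std::string& s, int k,
                 std::vector<uint64_t>& h, std::vector<char>& valid);

// sliding windows at 0, st, 2*st, ... plus one tail window anchored at L - s;
// sequences shorter than s are sketched as a single truncated window
std::vector<Mmz> sketch_seq(const std::string& seq, int k, int s, int st);

// ---- slot-array index ----

struct Posting {
  uint64_t hash;
  int32_t gene;   // gene ordinal within the IAR (0-based)
  int32_t off;    // 0-based offset within the gene's sense sequence
};

struct IarIndex {
  int64_t n_min = 0;     // number of minimizers inserted (pre-dedup), MI_j
  int64_t modulus = 1;   // home-slot modulus per the MI_j / mo rule
  std::vector<Posting> slots;
  std::vector<uint8_t> used;

  void build(const std::vector<Posting>& ps, int64_t mo);
  void insert(const Posting& p);
  void lookup(uint64_t h, std::vector<Posting>& out) const;
  int count_hash(uint64_t h) const;
};

struct MultiIndex {
  int k = 25, s = 40, st = 9;
  int64_t mo = 4096;
  int n_genes = 0;
  std::vector<IarIndex> iars;
  std::vector<std::vector<int32_t>> iar_genes;  // global 0-based gene ids
  std::vector<char> gene_strand;                // '+' or '-', by global id
};

}  // namespace rt

#endif
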