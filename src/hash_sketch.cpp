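#include <Rcpp.h>
#include "rt_core.h"

using namespace Rcpp;

namespace rt {

std::string hash_hex(uint64_t h) {
  static const char* d = "0123456789abcdef";
  std::string out(16, '0');
  for (int i = 15; i >= 0; --i) { out[i] = d[h & 0xf]; h >>= 4; }
  return out;
}

bool hex_to_u64(const std::string& s, uint64_t& out) {
  if (s.empty() || s.size() > 16) return false;
  out = 0;
  for (char c : s) {
    int v;
    if (c >= '0' && c <= '9') v = c - '0';
    else if (c >= 'a' && c <= 'f') v = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') v = c - 'A' + 10;
    else return false;
    out = (out << 4) | (uint64_t)v;
  }
  return true;
}

void kmer_hashes(const std::string& s, int k,
                 std::vector<uint64_t>& h, std::vector<char>& valid) {
  int L = (int)s.size();
  int n = L - k + 1;
  h.assign(std::max(n, 0), 0);
  valid.assign(std::max(n, 0), 0);
  if (n <= 0) return;
  uint64_t code = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // length of current unambiguous run ending at i
  for (int i = 0; i < L; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    ++run;
    if (run >= k) {
      int pos = i - k + 1;
      h[pos] = mix64(code);
      valid[pos] = 1;
    }
  }
}

std::vector<Mmz> sketch_seq(const std::string& seq, int k, int s, int st) {
  std::vector<Mmz> out;
  int L = (int)seq.size();
  if (L < k) return out;

  std::vector<uint64_t> h;
  std::vector<char> valid;
  kmer_hashes(seq, k, h, valid);

  std::vector<int> starts;
  int w = s;
  if (L < s) {
    starts.push_back(0);
    w = L;  // single truncated window
  } else {
    int last = -1;
    for (int x = 0; x + s <= L; x += st) { starts.push_back(x); last = x; }
    if (last >= 0 && last + s < L) starts.push_back(L - s);
  }

  for (int x : starts) {
    int nk = w - k + 1;
    int best = -1;
    uint64_t bh = 0;
    for (int j = 0; j < nk; ++j) {
      int pos = x + j;
      if (!valid[pos]) continue;
      if (best < 0 || h[pos] < bh) { best = pos; bh = h[pos]; }
    }
    if (best >= 0) out.push_back({bh, best});
  }

  // collapse duplicate (hash, offset) pairs, keep offset order
  std::sort(out.begin(), out.end(), [](const Mmz& a, const Mmz& b) {
    return a.off < b.off || (a.off == b.off && a.hash < b.hash);
  });
  out.erase(std::unique(out.begin(), out.end(), [](const Mmz& a, const Mmz& b) {
    return a.off == b.off && a.hash == b.hash;
  }), out.end());
  return out;
}

}  // namespace rt

// ---------------- R-facing helpers ----------------

// [[Rcpp::export]]
double rt_encode_kmer(std::string seq) {
  int k = (int)seq.size();
  if (k < 1 || k > 26)
    stop("numeric k-mer codes are exact only for 1 <= k <= 26");
  uint64_t code = 0;
  for (char c : seq) {
    int b = rt::base_code(c);
    if (b < 0) return NA_REAL;
    code = (code << 2) | (uint64_t)b;
  }
  return (double)code;
}

// [[Rcpp::export]]
CharacterVector rt_kmer_hash(CharacterVector kmers) {
  int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(kmers[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(kmers[i]);
    uint64_t code = 0;
    bool ok = s.size() >= 1 && s.size() <= 32;
    for (char c : s) {
      int b = rt::base_code(c);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)b;
    }
    if (ok) out[i] = rt::hash_hex(rt::mix64(code));
    else out[i] = NA_STRING;
  }
  return out;
}

// [[Rcpp::export]]
std::string rt_hash_code(double code) {
  if (code < 0 || code > 9007199254740992.0)
    stop("code must be a non-negative integer below 2^53");
  return rt::hash_hex(rt::mix64((uint64_t)code));
}

// [[Rcpp::export]]
std::string rt_hash_hex(std::string hex) {
  uint64_t x;
  if (!rt::hex_to_u64(hex, x)) stop("invalid hex word: %s", hex.c_str());
  return rt::hash_hex(rt::mix64(x));
}

// [[Rcpp::export]]
std::string rt_hash_invert(std::string hex) {
  uint64_t x;
  if (!rt::hex_to_u64(hex, x)) stop("invalid hex word: %s", hex.c_str());
  return rt::hash_hex(rt::unmix64(x));
}

// Monte-Carlo avalanche audit: mean Hamming distance between hash(x) and
// hash(x ^ random single bit) over n draws, using R's RNG.
// [[Rcpp::export]]
double rt_avalanche_audit(int n) {
  double total = 0;
  for (int i = 0; i < n; ++i) {
    uint64_t x = 0;
    for (int j = 0; j < 4; ++j)
      x = (x << 16) | (uint64_t)(unif_rand() * 65536.0);
    int bit = (int)(unif_rand() * 64.0);
    if (bit > 63) bit = 63;
    uint64_t d = rt::mix64(x) ^ rt::mix64(x ^ (1ULL << bit));
#if defined(__GNUC__) || defined(__clang__)
    total += __builtin_popcountll(d);
#else
    int c = 0; while (d) { c += (int)(d & 1); d >>= 1; }
    total += c;
#endif
  }
  return total / n;
}

// [[Rcpp::export]]
std::string rt_revcomp(std::string seq) { return rt::revcomp(seq); }

// [[Rcpp::export]]
List rt_window_minimizer(std::string window, int k) {
  auto mm = rt::sketch_seq(window, k, (int)window.size(), 1);
  if (mm.empty())
    return List::create(_["hash"] = CharacterVector(0),
                        _["offset"] = IntegerVector(0));
  // a single window yields at most one minimizer
  return List::create(_["hash"] = rt::hash_hex(mm[0].hash),
                      _["offset"] = mm[0].off);
}

// [[Rcpp::export]]
DataFrame rt_sketch(std::string seq, int k, int s, int st) {
  auto mm = rt::sketch_seq(seq, k, s, st);
  int n = (int)mm.size();
  CharacterVector hash(n);
  IntegerVector off(n);
  for (int i = 0; i < n; ++i) {
    hash[i] = rt::hash_hex(mm[i].hash);
    off[i] = mm[i].off;
  }
  return DataFrame::create(_["hash"] = hash, _["offset"] = off,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame rt_sketch_read(std::string seq, int k, int s, int st) {
  auto fw = rt::sketch_seq(seq, k, s, st);
  auto rv = rt::sketch_seq(rt::revcomp(seq), k, s, st);
  int n = (int)(fw.size() + rv.size());
  CharacterVector hash(n), strand(n);
  IntegerVector off(n);
  int i = 0;
  for (auto& m : fw) { hash[i] = rt::hash_hex(m.hash); off[i] = m.off; strand[i] = "+"; ++i; }
  for (auto& m : rv) { hash[i] = rt::hash_hex(m.hash); off[i] = m.off; strand[i] = "-"; ++i; }
  return DataFrame::create(_["hash"] = hash, _["offset"] = off,
                           _["strand"] = strand, _["stringsAsFactors"] = false);
}
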