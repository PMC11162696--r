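#include <Rcpp.h>
#include "rt_core.h"

using namespace Rcpp;

namespace rt {

void IarIndex::build(const std::vector<Posting>& ps, int64_t mo) {
  n_min = (int64_t)ps.size();
  modulus = (n_min >= mo) ? n_min : mo;
  if (modulus < 1) modulus = 1;
  // capacity slack keeps linear probing short and the table never full
  size_t cap = (size_t)std::ceil(1.3 * (double)std::max<int64_t>(n_min, mo)) + 4;
  slots.assign(cap, Posting{0, 0, 0});
  used.assign(cap, 0);
  for (const auto& p : ps) insert(p);
}

void IarIndex::insert(const Posting& p) {
  size_t cap = slots.size();
  size_t i = (size_t)(p.hash % (uint64_t)modulus);
  while (used[i]) {
    if (slots[i].hash == p.hash && slots[i].gene == p.gene && slots[i].off == p.off)
      return;  // identical posting stored once
    i = (i + 1) % cap;
  }
  slots[i] = p;
  used[i] = 1;
}

void IarIndex::lookup(uint64_t h, std::vector<Posting>& out) const {
  size_t cap = slots.size();
  if (cap == 0) return;
  size_t i = (size_t)(h % (uint64_t)modulus);
  size_t seen = 0;
  while (used[i] && seen < cap) {
    if (slots[i].hash == h) out.push_back(slots[i]);
    i = (i + 1) % cap;
    ++seen;
  }
}

int IarIndex::count_hash(uint64_t h) const {
  size_t cap = slots.size();
  if (cap == 0) return 0;
  size_t i = (size_t)(h % (uint64_t)modulus);
  size_t seen = 0;
  int c = 0;
  while (used[i] && seen < cap) {
    if (slots[i].hash == h) ++c;
    i = (i + 1) % cap;
    ++seen;
  }
  return c;
}

// ---- byte-writer helpers for serialization ----
static void put_u64(std::vector<uint8_t>& b, uint64_t v) {
  for (int i = 0; i < 8; ++i) { b.push_back((uint8_t)(v & 0xff)); v >>= 8; }
}
static void put_i32(std::vector<uint8_t>& b, int32_t v) {
  uint32_t u = (uint32_t)v;
  for (int i = 0; i < 4; ++i) { b.push_back((uint8_t)(u & 0xff)); u >>= 8; }
}
static uint64_t get_u64(const uint8_t*& p) {
  uint64_t v = 0;
  for (int i = 0; i < 8; ++i) v |= ((uint64_t)p[i]) << (8 * i);
  p += 8;
  return v;
}
static int32_t get_i32(const uint8_t*& p) {
  uint32_t v = 0;
  for (int i = 0; i < 4; ++i) v |= ((uint32_t)p[i]) << (8 * i);
  p += 4;
  return (int32_t)v;
}

}  // namespace rt

using rt::IarIndex;
using rt::MultiIndex;
using rt::Posting;

static std::vector<Posting> postings_from_r(CharacterVector hash,
                                            IntegerVector gene,
                                            IntegerVector off) {
  int n = hash.size();
  if (gene.size() != n || off.size() != n)
    stop("hash, gene and offset must have equal length");
  std::vector<Posting> ps(n);
  for (int i = 0; i < n; ++i) {
    uint64_t h;
    if (!rt::hex_to_u64(as<std::string>(hash[i]), h))
      stop("invalid hex hash at position %d", i + 1);
    ps[i] = {h, gene[i], off[i]};
  }
  return ps;
}

// [[Rcpp::export]]
SEXP rt_build_single(CharacterVector hash, IntegerVector gene,
                     IntegerVector off, double mo) {
  XPtr<IarIndex> xp(new IarIndex(), true);
  xp->build(postings_from_r(hash, gene, off), (int64_t)mo);
  return xp;
}

static DataFrame postings_df(const std::vector<Posting>& out) {
  int n = (int)out.size();
  CharacterVector hash(n);
  IntegerVector gene(n), off(n);
  for (int i = 0; i < n; ++i) {
    hash[i] = rt::hash_hex(out[i].hash);
    gene[i] = out[i].gene;
    off[i] = out[i].off;
  }
  return DataFrame::create(_["hash"] = hash, _["gene"] = gene,
                           _["offset"] = off, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame rt_single_query(SEXP ptr, std::string hex) {
  XPtr<IarIndex> xp(ptr);
  uint64_t h;
  if (!rt::hex_to_u64(hex, h)) stop("invalid hex hash");
  std::vector<Posting> out;
  xp->lookup(h, out);
  return postings_df(out);
}

// [[Rcpp::export]]
List rt_single_stats(SEXP ptr) {
  XPtr<IarIndex> xp(ptr);
  return List::create(_["n_minimizers"] = (double)xp->n_min,
                      _["modulus"] = (double)xp->modulus,
                      _["capacity"] = (double)xp->slots.size());
}

// [[Rcpp::export]]
SEXP rt_build_multi(CharacterVector gene_seqs, IntegerVector iar_of_gene,
                    CharacterVector strand, int k, int s, int st, double mo) {
  int n = gene_seqs.size();
  if (iar_of_gene.size() != n || strand.size() != n)
    stop("gene_seqs, iar_of_gene and strand must have equal length");
  XPtr<MultiIndex> xp(new MultiIndex(), true);
  xp->k = k; xp->s = s; xp->st = st; xp->mo = (int64_t)mo;
  xp->n_genes = n;
  xp->gene_strand.resize(n);

  int n_iars = 0;
  for (int i = 0; i < n; ++i) n_iars = std::max(n_iars, iar_of_gene[i]);
  xp->iars.resize(n_iars);
  xp->iar_genes.assign(n_iars, {});

  std::vector<std::vector<Posting>> ps(n_iars);
  for (int g = 0; g < n; ++g) {
    int j = iar_of_gene[g] - 1;
    if (j < 0) stop("iar_of_gene must be 1-based positive");
    std::string sc = as<std::string>(strand[g]);
    xp->gene_strand[g] = sc.empty() ? '+' : sc[0];
    int ord = (int)xp->iar_genes[j].size();
    xp->iar_genes[j].push_back(g);
    auto sk = rt::sketch_seq(as<std::string>(gene_seqs[g]), k, s, st);
    for (auto& m : sk) ps[j].push_back({m.hash, ord, m.off});
  }
  for (int j = 0; j < n_iars; ++j) xp->iars[j].build(ps[j], xp->mo);
  return xp;
}

// [[Rcpp::export]]
List rt_multi_stats(SEXP ptr) {
  XPtr<MultiIndex> xp(ptr);
  int M = (int)xp->iars.size();
  NumericVector n_min(M), modulus(M), capacity(M);
  IntegerVector n_genes(M), iar(M);
  for (int j = 0; j < M; ++j) {
    iar[j] = j + 1;
    n_min[j] = (double)xp->iars[j].n_min;
    modulus[j] = (double)xp->iars[j].modulus;
    capacity[j] = (double)xp->iars[j].slots.size();
    n_genes[j] = (int)xp->iar_genes[j].size();
  }
  return List::create(
      _["params"] = List::create(_["k"] = xp->k, _["s"] = xp->s,
                                 _["st"] = xp->st, _["mo"] = (double)xp->mo),
      _["iars"] = DataFrame::create(_["iar"] = iar, _["n_genes"] = n_genes,
                                    _["n_minimizers"] = n_min,
                                    _["modulus"] = modulus,
                                    _["capacity"] = capacity));
}

// [[Rcpp::export]]
DataFrame rt_multi_query(SEXP ptr, int iar, std::string hex) {
  XPtr<MultiIndex> xp(ptr);
  if (iar < 1 || iar > (int)xp->iars.size()) stop("iar out of range");
  uint64_t h;
  if (!rt::hex_to_u64(hex, h)) stop("invalid hex hash");
  std::vector<Posting> out;
  xp->iars[iar - 1].lookup(h, out);
  return postings_df(out);
}

// all postings across IARs (slot order), for set-equality oracles
// [[Rcpp::export]]
DataFrame rt_multi_postings(SEXP ptr) {
  XPtr<MultiIndex> xp(ptr);
  std::vector<int> iar_v;
  std::vector<Posting> out;
  for (size_t j = 0; j < xp->iars.size(); ++j) {
    const IarIndex& ix = xp->iars[j];
    for (size_t i = 0; i < ix.slots.size(); ++i)
      if (ix.used[i]) { iar_v.push_back((int)j + 1); out.push_back(ix.slots[i]); }
  }
  int n = (int)out.size();
  IntegerVector iar(n), gene(n), off(n);
  CharacterVector hash(n);
  for (int i = 0; i < n; ++i) {
    iar[i] = iar_v[i];
    hash[i] = rt::hash_hex(out[i].hash);
    gene[i] = out[i].gene;
    off[i] = out[i].off;
  }
  return DataFrame::create(_["iar"] = iar, _["hash"] = hash, _["gene"] = gene,
                           _["offset"] = off, _["stringsAsFactors"] = false);
}

// versioned binary serialization; bit-exact round trip
// [[Rcpp::export]]
RawVector rt_serialize(SEXP ptr) {
  XPtr<MultiIndex> xp(ptr);
  std::vector<uint8_t> b;
  const char magic[6] = {'R', 'T', 'I', 'X', '0', '1'};
  for (char c : magic) b.push_back((uint8_t)c);
  rt::put_i32(b, xp->k); rt::put_i32(b, xp->s); rt::put_i32(b, xp->st);
  rt::put_u64(b, (uint64_t)xp->mo);
  rt::put_i32(b, xp->n_genes);
  rt::put_i32(b, (int32_t)xp->iars.size());
  for (int g = 0; g < xp->n_genes; ++g) b.push_back((uint8_t)xp->gene_strand[g]);
  for (size_t j = 0; j < xp->iars.size(); ++j) {
    rt::put_i32(b, (int32_t)xp->iar_genes[j].size());
    for (int32_t g : xp->iar_genes[j]) rt::put_i32(b, g);
    const IarIndex& ix = xp->iars[j];
    rt::put_u64(b, (uint64_t)ix.n_min);
    rt::put_u64(b, (uint64_t)ix.modulus);
    rt::put_u64(b, (uint64_t)ix.slots.size());
    for (size_t i = 0; i < ix.slots.size(); ++i) {
      b.push_back(ix.used[i]);
      rt::put_u64(b, ix.slots[i].hash);
      rt::put_i32(b, ix.slots[i].gene);
      rt::put_i32(b, ix.slots[i].off);
    }
  }
  RawVector out(b.size());
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
SEXP rt_deserialize(RawVector raw) {
  if (raw.size() < 6 + 12 + 8 + 8) stop("truncated index blob");
  const uint8_t* p = RAW(raw);
  const char magic[6] = {'R', 'T', 'I', 'X', '0', '1'};
  for (int i = 0; i < 6; ++i)
    if ((char)p[i] != magic[i]) stop("not a readthroughr index blob");
  p += 6;
  XPtr<MultiIndex> xp(new MultiIndex(), true);
  xp->k = rt::get_i32(p); xp->s = rt::get_i32(p); xp->st = rt::get_i32(p);
  xp->mo = (int64_t)rt::get_u64(p);
  xp->n_genes = rt::get_i32(p);
  int M = rt::get_i32(p);
  xp->gene_strand.resize(xp->n_genes);
  for (int g = 0; g < xp->n_genes; ++g) xp->gene_strand[g] = (char)*p++;
  xp->iars.resize(M);
  xp->iar_genes.assign(M, {});
  for (int j = 0; j < M; ++j) {
    int ng = rt::get_i32(p);
    xp->iar_genes[j].resize(ng);
    for (int i = 0; i < ng; ++i) xp->iar_genes[j][i] = rt::get_i32(p);
    IarIndex& ix = xp->iars[j];
    ix.n_min = (int64_t)rt::get_u64(p);
    ix.modulus = (int64_t)rt::get_u64(p);
    size_t cap = (size_t)rt::get_u64(p);
    ix.slots.assign(cap, Posting{0, 0, 0});
    ix.used.assign(cap, 0);
    for (size_t i = 0; i < cap; ++i) {
      ix.used[i] = *p++;
      ix.slots[i].hash = rt::get_u64(p);
      ix.slots[i].gene = rt::get_i32(p);
      ix.slots[i].off = rt::get_i32(p);
    }
  }
  return xp;
}
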