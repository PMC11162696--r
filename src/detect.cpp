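#include <Rcpp.h>
#include <climits>
#include "rt_core.h"

using namespace Rcpp;
using rt::MultiIndex;
using rt::IarIndex;
using rt::Posting;
using rt::Mmz;

// one minimizer hit tuple inside one IAR
struct Hit {
  int32_t ro;    // read offset (chosen orientation)
  int32_t gene;  // gene ordinal within IAR
  int32_t go;    // offset within gene sense sequence
};

// number of read minimizers whose hash is present in the index
static int screen_hits(const IarIndex& ix, const std::vector<Mmz>& sk) {
  int c = 0;
  for (const auto& m : sk)
    if (ix.count_hash(m.hash) > 0) ++c;
  return c;
}

// hit tuples with the repetitive-hash filter applied
static std::vector<Hit> gather_hits(const IarIndex& ix,
                                    const std::vector<Mmz>& sk, int rep_max) {
  std::vector<Hit> hits;
  std::vector<Posting> out;
  for (const auto& m : sk) {
    out.clear();
    ix.lookup(m.hash, out);
    if (out.empty() || (int)out.size() > rep_max) continue;
    for (const auto& p : out) hits.push_back({m.off, p.gene, p.off});
  }
  return hits;
}

struct PairCall {
  bool ok = false;
  int up = -1, down = -1;      // gene ordinals within IAR
  int up_hits = 0, down_hits = 0;
  double transition = NA_REAL;
  char strand = '+';
};

// evaluate one transcriptionally adjacent pair (ordinals a < b genomically)
static PairCall eval_pair(const std::vector<Hit>& hits, int a, int b,
                          char strand, int per_gene_min, double order_frac,
                          double mono_frac) {
  PairCall pc;
  int up = (strand == '+') ? a : b;    // transcription order
  int down = (strand == '+') ? b : a;
  std::vector<const Hit*> hu, hd;
  for (const auto& h : hits) {
    if (h.gene == up) hu.push_back(&h);
    else if (h.gene == down) hd.push_back(&h);
  }
  if ((int)hu.size() < per_gene_min || (int)hd.size() < per_gene_min) return pc;

  // order consistency: upstream hits precede downstream hits on the read
  long conc = 0, tot = 0;
  for (const auto* u : hu)
    for (const auto* d : hd) {
      if (u->ro == d->ro) continue;
      ++tot;
      if (u->ro < d->ro) ++conc;
    }
  if (tot > 0 && (double)conc / tot < order_frac) return pc;

  // within-gene co-monotonicity of read offsets and gene offsets
  for (const std::vector<const Hit*>* hv : {&hu, &hd}) {
    long c = 0, t = 0;
    int n = (int)hv->size();
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        const Hit* x = (*hv)[i];
        const Hit* y = (*hv)[j];
        if (x->ro == y->ro || x->go == y->go) continue;
        ++t;
        long d = (long)(y->ro - x->ro) * (long)(y->go - x->go);
        if (d > 0) ++c;
      }
    if (t > 0 && (double)c / t < mono_frac) return pc;
  }

  // transition estimate: midpoint of the flanking concordant hits
  int u_max = -1, d_min = -1, u_all_max = -1, d_all_min = -1;
  for (const auto* d : hd) {
    if (d_all_min < 0 || d->ro < d_all_min) d_all_min = d->ro;
  }
  for (const auto* u : hu) {
    if (u_all_max < 0 || u->ro > u_all_max) u_all_max = u->ro;
  }
  for (const auto* u : hu)
    if (u->ro < d_all_min || d_all_min < 0)
      u_max = std::max(u_max, u->ro);
  for (const auto* d : hd)
    if (d->ro > u_all_max || u_all_max < 0)
      d_min = (d_min < 0) ? d->ro : std::min(d_min, d->ro);
  if (u_max < 0) u_max = u_all_max;
  if (d_min < 0) d_min = d_all_min;

  pc.ok = true;
  pc.up = up; pc.down = down;
  pc.up_hits = (int)hu.size();
  pc.down_hits = (int)hd.size();
  pc.transition = (u_max + d_min) / 2.0;
  pc.strand = strand;
  return pc;
}

// best confirmed adjacent pair within one IAR, or ok=false
static PairCall confirm_iar(const MultiIndex& mi, int j,
                            const std::vector<Hit>& hits, int per_gene_min,
                            double order_frac, double mono_frac,
                            bool same_strand) {
  const auto& genes = mi.iar_genes[j];
  int ng = (int)genes.size();
  PairCall best;
  int best_score = -1;
  for (int a = 0; a + 1 < ng; ++a) {
    char sa = mi.gene_strand[genes[a]];
    char sb = mi.gene_strand[genes[a + 1]];
    if (same_strand && sa != sb) continue;
    PairCall pc = eval_pair(hits, a, a + 1, sa, per_gene_min, order_frac,
                            mono_frac);
    if (!pc.ok) continue;
    int score = std::min(pc.up_hits, pc.down_hits);
    if (score > best_score) {  // tie keeps the 5'-most (lowest ordinal) pair
      best_score = score;
      best = pc;
    }
  }
  return best;
}

// [[Rcpp::export]]
List rt_screen(SEXP ptr, std::string read, int screen_min_hits) {
  XPtr<MultiIndex> xp(ptr);
  auto fw = rt::sketch_seq(read, xp->k, xp->s, xp->st);
  auto rv = rt::sketch_seq(rt::revcomp(read), xp->k, xp->s, xp->st);
  int M = (int)xp->iars.size();
  std::vector<int> hf(M), hr(M);
  long tf = 0, tr = 0;
  for (int j = 0; j < M; ++j) {
    hf[j] = screen_hits(xp->iars[j], fw);
    hr[j] = screen_hits(xp->iars[j], rv);
    tf += hf[j];
    tr += hr[j];
  }
  bool fwd = tf >= tr;
  const auto& sk = fwd ? fw : rv;
  const auto& hh = fwd ? hf : hr;
  List cands;
  for (int j = 0; j < M; ++j) {
    if (hh[j] < screen_min_hits) continue;
    auto hits = gather_hits(xp->iars[j], sk, INT_MAX);
    int ng = (int)xp->iar_genes[j].size();
    IntegerVector per_gene(ng);
    for (const auto& h : hits) per_gene[h.gene] = per_gene[h.gene] + 1;
    int n = (int)hits.size();
    IntegerVector ro(n), gene(n), go(n);
    for (int i = 0; i < n; ++i) {
      ro[i] = hits[i].ro; gene[i] = hits[i].gene + 1; go[i] = hits[i].go;
    }
    cands.push_back(List::create(
        _["iar"] = j + 1,
        _["strand"] = fwd ? "+" : "-",
        _["total_hits"] = hh[j],
        _["per_gene_hits"] = per_gene,
        _["hits"] = DataFrame::create(_["read_offset"] = ro,
                                      _["gene_ordinal"] = gene,
                                      _["gene_offset"] = go)));
  }
  return cands;
}

// [[Rcpp::export]]
DataFrame rt_detect(SEXP ptr, CharacterVector reads, CharacterVector ids,
                    int screen_min_hits, int per_gene_min_hits,
                    double order_frac, double mono_frac, int rep_max,
                    bool same_strand) {
  XPtr<MultiIndex> xp(ptr);
  int M = (int)xp->iars.size();
  int nr = reads.size();
  if (ids.size() != nr) stop("reads and ids must have equal length");

  std::vector<std::string> o_id, o_strand, o_gstrand;
  std::vector<int> o_iar, o_up, o_down, o_uh, o_dh;
  std::vector<double> o_tr;

  std::vector<int> hf(M), hr(M);
  for (int r = 0; r < nr; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    std::string seq = as<std::string>(reads[r]);
    auto fw = rt::sketch_seq(seq, xp->k, xp->s, xp->st);
    auto rv = rt::sketch_seq(rt::revcomp(seq), xp->k, xp->s, xp->st);
    long tf = 0, tr = 0;
    for (int j = 0; j < M; ++j) {
      hf[j] = screen_hits(xp->iars[j], fw);
      hr[j] = screen_hits(xp->iars[j], rv);
      tf += hf[j];
      tr += hr[j];
    }
    bool fwd = tf >= tr;
    const auto& sk = fwd ? fw : rv;
    const auto& hh = fwd ? hf : hr;

    PairCall best;
    int best_iar = -1, best_score = -1;
    for (int j = 0; j < M; ++j) {
      if (hh[j] < screen_min_hits) continue;
      auto hits = gather_hits(xp->iars[j], sk, rep_max);
      PairCall pc = confirm_iar(*xp, j, hits, per_gene_min_hits, order_frac,
                                mono_frac, same_strand);
      if (!pc.ok) continue;
      int score = std::min(pc.up_hits, pc.down_hits);
      if (score > best_score) {
        best_score = score;
        best = pc;
        best_iar = j;
      }
    }
    if (best_iar < 0) continue;
    const auto& genes = xp->iar_genes[best_iar];
    o_id.push_back(as<std::string>(ids[r]));
    o_iar.push_back(best_iar + 1);
    o_up.push_back(genes[best.up] + 1);     // global 1-based gene id
    o_down.push_back(genes[best.down] + 1);
    o_uh.push_back(best.up_hits);
    o_dh.push_back(best.down_hits);
    o_tr.push_back(best.transition);
    o_strand.push_back(fwd ? "+" : "-");
    o_gstrand.push_back(std::string(1, best.strand));
  }

  return DataFrame::create(
      _["read_id"] = wrap(o_id), _["iar"] = wrap(o_iar),
      _["up_gene"] = wrap(o_up), _["down_gene"] = wrap(o_down),
      _["up_hits"] = wrap(o_uh), _["down_hits"] = wrap(o_dh),
      _["transition"] = wrap(o_tr), _["read_strand"] = wrap(o_strand),
      _["gene_strand"] = wrap(o_gstrand), _["stringsAsFactors"] = false);
}
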