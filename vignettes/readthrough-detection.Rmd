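---
title: "Detecting read-through transcripts with minimizer sketches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting read-through transcripts with minimizer sketches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In gene-dense regions of a genome, RNA polymerase sometimes ignores the
termination signal of an upstream gene and continues through the intergenic
region into the next gene. The product is a *read-through* (conjoined-gene)
transcript that carries exons of two neighboring genes. Short-read pipelines
tend to split such molecules into independent upstream and downstream
fragments, so read-throughs went under-reported for years. Long reads carry
the whole molecule, but at error rates that defeat exact matching.

`readthroughr` detects read-through transcripts directly from long reads
(FASTA/FASTQ) given a reference genome and a gene annotation, and ships two
downstream tools: an NMD/protein-coding fate predictor based on the 55-nt
exon-junction rule, and a splice-pattern exporter (BED12 plus a block
figure). A synthetic-data module generates fully labelled toy benchmarks.

## The method

**1. Isolated active regions (IARs).** Genes are ordered by genomic start
and split, per chromosome, wherever the intergenic gap
`start[i+1] - end[i]` exceeds a threshold `thr` (default 100 kb, motivated
by the observation that distances between annotated conjoined-gene partners
almost all fall below 100 kb). Within an IAR every consecutive gap is at
most `thr`; between IARs lies a gene desert. Read-through partners are by
definition adjacent within one IAR, so all later work is region-local, and
regions are independent work units (the index build shares no state across
IARs). Partitioning is strand-blind; strand is enforced at call time.
Overlapping genes always share a region.

**2. Minimizer sketching.** Each gene's annotated-strand genomic sequence is
scanned with windows of length `s` at step `st`; in every window the k-mer
with the smallest hash is kept (the window's *minimizer*). The hash is a
bijective 64-bit multiply–xorshift avalanche mix, so distinct k-mers never
collide and one flipped input bit flips about half the output bits (audited
in the tests at 32 ± 2). Defaults are `k = 25`, `s = 40`, `st = 9`; the
`noisy` preset (`k = 15`, `s = 24`, `st = 9`) trades specificity for error
tolerance. If the last full window does not reach the sequence end, one
extra window is anchored at `length - s`, so 3' ends are never unsketched —
losing terminal exons would directly hurt breakpoint-adjacent evidence.
K-mers containing ambiguous bases are skipped deterministically rather than
randomized. The reference sketches only the annotated strand; the query
side compensates by sketching both read orientations, which halves index
size and keeps the hash bijective (a strand-canonical hash cannot be).

**3. The slot-array index.** Per IAR, the `MI_j` minimizers are stored in
one contiguous array. The home slot of a minimizer is `hash mod MI_j` when
`MI_j >= mo`, and `hash mod mo` otherwise (`mo` defaults to 4096 slots;
without the floor, a one-gene region with a few dozen minimizers would get
a degenerate, collision-heavy modulus). Collisions are resolved by linear
probing into a capacity of `1.3 x max(MI_j, mo)` slots, preserving the
contiguous-memory rationale while guaranteeing that every inserted posting
remains retrievable; identical postings are stored once. Builds are pure
functions of their inputs and the versioned binary serialization
round-trips bit-exactly.

**4. Two-stage detection.** Screening counts, per region, how many of a
read's minimizers occur in the region's index; the read's orientation is
fixed once here (the orientation with more total hits) and regions below
`screen_min_hits` (default 3) are discarded — this removes the vast
majority of single-gene reads cheaply. Confirmation then requires, for two
transcriptionally adjacent same-strand genes: at least `per_gene_min_hits`
(default 2) hits in each gene; upstream hits preceding downstream hits on
the read for at least `order_frac` (0.75) of cross-gene hit pairs; and
read/gene offsets co-monotone within each gene for at least `mono_frac`
(0.75) of pairs. Minimizers occurring in more than `rep_max` (16) postings
within a region are ignored — unfiltered repeats break order consistency.
"Upstream" means transcription order: for a minus-strand pair the
genomically-right gene is upstream. Defaults favor sensitivity because
long-read data sets are typically shallow; every threshold is exposed.
Confirmed reads are aggregated per gene pair and pairs with fewer than
`min_support` (default 1) supporting reads are dropped. The breakpoint
estimate is the median per-read transition offset (midpoint between the
last concordant upstream hit and the first concordant downstream hit).

**5. NMD fate.** For each call the supporting reads are oriented and
anchored: one semi-global edit-distance DP locates where the upstream
spliced transcript ends inside the read (its 5' end may be truncated for
free), a mirrored DP locates where the downstream transcript starts, and
the segment between is the intergenic insert candidate. Reads whose
anchoring distance exceeds `max(20, 0.2 x aligned length)` are excluded.
This replaces the literal exon-by-exon walk with an equivalent one-shot
DP; the boundary exon is the last upstream exon. One subtlety found during
development: with free transcript clipping the DP must maximize an
alignment score (match +1, mismatch/gap −2, ties toward the largest text
position) rather than minimize edit distance — under a distance objective
a chance match of the transcript's last base near the read start costs 0
and always beats the true junction, whose cost grows with the read's
error rate. The reported anchoring cost is the score deficit converted
back to error-equivalent units for the band check. Insert segments are "reciprocally
corrected" by a medoid-backbone star alignment: the segment with minimum
total edit distance to the others anchors the alignment, columns are
majority-voted (ties toward the backbone), and insertions relative to the
backbone are adopted when a majority of segments insert at the same gap.
The fused model (upstream exons + insert + downstream exons) is translated
in the upstream CDS frame; the first in-frame stop at or after the boundary
exon is the candidate PTC, and the transcript is NMD-prone exactly when
that stop lies more than 55 nt upstream of the fused model's last
exon–exon junction (55 exactly escapes; distance measured from the stop's
last base in spliced coordinates). An empty insert implies a clean splice
junction at the boundary, which counts as a junction; a retained insert is
contiguous with its flanking exons and contributes none. A fused model with
no junction at all cannot trigger NMD and is reported protein-coding with a
note, as are transcripts whose only stop lies past the last junction; a
missing upstream CDS yields `indeterminate`.

**6. Splice-pattern export.** The window from the upstream TSS to the
downstream TTS is extracted and each supporting read (or consensus) is
locally aligned to it with near-free gap extension so that multi-kb introns
are affordable; region gaps of at least `min_intron` (30 bp) collapse into
introns and the result is written as BED12 (0-based half-open; all
conversions from the 1-based annotation go through one pair of functions).
A minimal deterministic exon-block figure accompanies each BED file.

## The synthetic benchmark

`sim_config()` states the emulated world: 2 chromosomes x 20 multi-exon
coding genes (~50 transcripts), 10 disjoint adjacent same-strand pairs
carrying a read-through isoform, equal expression for all transcripts,
x100 depth, per-read length-coverage drawn uniformly above a floor
(0.5/0.75/0.9/0.95 in the benchmark grid), 5'- or 3'-anchored with equal
probability, random orientation, and either perfect reads or i.i.d.
per-base errors at 2% substitution / 3% insertion / 3% deletion
(approximating ONT-class error). Exon counts (2–5), exon lengths
(150–450 bp), introns (0.3–1.5 kb) and gaps (2–20 kb, with a 10% chance of
a >100 kb desert so partitioning is exercised) were chosen once as
plausible compact-gene values; they are not tuned. Every gene gets a clean
ORF so the fate module has a defined frame, and the generator's GTF/FASTA
round-trip through the package's own parser is itself a test oracle.

What the generator does *not* emulate: trained ONT error profiles (errors
here are i.i.d., with no homopolymer bias), quality-score realism,
expression variability, alternative isoforms, or genomic repeats. A green
benchmark therefore establishes correctness of the machinery under the
stated noise model, not field performance on real flowcell data; the
erroneous-mode bound is a scaled-down surrogate by construction.

## Numerical and design choices

- Hash ties inside a window are impossible between distinct k-mers
  (bijectivity); duplicate k-mers take the leftmost position.
- The anchor DP and `rt_edit_distance` use unit costs; the anchoring band
  is applied after the DP rather than inside it (read lengths here make
  full DP affordable).
- In `consensus_insert`, an all-empty segment set (clean splice junctions)
  short-circuits to an empty consensus.
- The simulator writes CDS rows including the stop codon; the parser takes
  min/max spans only, and the fate module needs the full frame, so
  nothing downstream observes the difference from strict GTF.
- `compute_metrics` scores ordered pairs: a swapped (downstream, upstream)
  call is a false positive.
- Degenerate inputs: genes shorter than `k` sketch empty (logged); reads
  shorter than `k` never match; an empty annotation partitions to zero
  regions; `min_support = 0` reports every confirmed pair.

## Known limitations

- Inter-chromosomal and structural-variant fusions are out of scope by
  design; so is base-precise breakpoint refinement by full alignment.
- The per-IAR screen is linear in the number of regions per read; for
  genome-scale annotations an inverted hash-to-region map would be the
  next optimization.
- Only the union-exon gene model is supported (no per-transcript models);
  GFF3 is not parsed.
- The star-alignment consensus is a cheap scheme; a POA graph would be
  more accurate on very noisy inserts.
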