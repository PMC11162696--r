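# NMD fate: anchoring, consensus correction, and the 55-nt rule

test_that("classify_fate applies the 55-nt rule (NMD case)", {
  # downstream: two 60-nt A-free exons; insert carries an in-frame TAA
  # whose last base sits 116 nt upstream of the last junction
  w <- fate_world(down_mrna = gc_filler(120))
  insert <- paste0(substr(gc_filler(60), 1, 1), "TAA", gc_filler(56))
  up <- w$genes[w$genes$gene_id == "UP", , drop = FALSE]
  down <- w$genes[w$genes$gene_id == "DN", , drop = FALSE]
  res <- classify_fate(up, down, insert, w$genome)
  expect_true(res$ptc_found)
  expect_equal(res$stop_codon, "TAA")
  # fused: up 120 + insert 60 + down 120; junctions 60, 240; PTC end 124
  expect_equal(res$distance_to_last_junction, 116)
  expect_equal(res$classification, "NMD")
})

test_that("a stop within 55 nt of the last junction escapes NMD", {
  down <- paste0(substr(gc_filler(28), 1, 28), "TAA", gc_filler(89))
  w <- fate_world(down_mrna = down)
  # fused: up 120 + insert 60 + down 120; stop at down offset 29..31 ->
  # fused end 211; last junction 240; distance 29 <= 55
  insert <- gc_filler(60)
  res <- classify_fate(w$genes[1, ], w$genes[2, ], insert, w$genome)
  expect_true(res$ptc_found)
  expect_equal(res$distance_to_last_junction, 29)
  expect_equal(res$classification, "protein_coding")
})

test_that("no stop before the downstream gene's own stop is protein-coding", {
  # empty insert: clean splice at the boundary; downstream stop in its
  # last exon, i.e. after the last junction
  down <- paste0(gc_filler(70), "TGA", gc_filler(47))
  w <- fate_world(down_mrna = down)
  res <- classify_fate(w$genes[1, ], w$genes[2, ], "", w$genome)
  # fused: up 120 + down 120; junctions 60, 120, 180; stop ends at 193
  expect_true(res$ptc_found)
  expect_equal(res$distance_to_last_junction, 180 - 193)
  expect_equal(res$classification, "protein_coding")
})

test_that("distances bracketing the 55-nt boundary flip the class", {
  # fused: up 120 + insert 60 + down 120; last junction 240; the reading
  # frame admits fused codon starts p with (p - 11) %% 3 == 0, so the
  # distances closest to the boundary are 56 (NMD) and 53 (escape)
  mk <- function(down_off) {  # 1-based stop-codon start within down mRNA
    down <- paste0(substr(gc_filler(60), 1, down_off - 1), "TAA",
                   gc_filler(120 - down_off - 2))
    fate_world(down_mrna = down)
  }
  w_nmd <- mk(2)   # fused start 182, ptc_end 184, distance 56
  r_nmd <- classify_fate(w_nmd$genes[1, ], w_nmd$genes[2, ], gc_filler(60),
                         w_nmd$genome)
  expect_equal(r_nmd$distance_to_last_junction, 56)
  expect_equal(r_nmd$classification, "NMD")

  w_esc <- mk(5)   # fused start 185, ptc_end 187, distance 53
  r_esc <- classify_fate(w_esc$genes[1, ], w_esc$genes[2, ], gc_filler(60),
                         w_esc$genome)
  expect_equal(r_esc$distance_to_last_junction, 53)
  expect_equal(r_esc$classification, "protein_coding")
})

test_that("a missing upstream CDS gives an indeterminate classification", {
  w <- fate_world(down_mrna = gc_filler(120))
  up <- w$genes[1, , drop = FALSE]
  up$cds_start <- NA_integer_
  up$cds_end <- NA_integer_
  res <- classify_fate(up, w$genes[2, ], "", w$genome)
  expect_equal(res$classification, "indeterminate")
})

test_that("minus-strand gene models classify identically", {
  w_plus <- fate_world(down_mrna = gc_filler(120), strand = "+")
  w_minus <- fate_world(down_mrna = gc_filler(120), strand = "-")
  insert <- paste0(substr(gc_filler(60), 1, 1), "TAA", gc_filler(56))
  r1 <- classify_fate(w_plus$genes[w_plus$genes$gene_id == "UP", ],
                      w_plus$genes[w_plus$genes$gene_id == "DN", ],
                      insert, w_plus$genome)
  r2 <- classify_fate(w_minus$genes[w_minus$genes$gene_id == "UP", ],
                      w_minus$genes[w_minus$genes$gene_id == "DN", ],
                      insert, w_minus$genome)
  expect_equal(r2$classification, r1$classification)
  expect_equal(r2$distance_to_last_junction, r1$distance_to_last_junction)
})

test_that("consensus_insert majority-votes errors away", {
  segs <- c("ACGTACGT", "ACGTACGT", "ACCTACGT")  # one substitution
  expect_equal(consensus_insert(segs), "ACGTACGT")
  expect_equal(consensus_insert("TTTT"), "TTTT")  # single segment unchanged
  expect_error(consensus_insert(character(0)))
  expect_equal(consensus_insert(c("", "", "ACGT")), "")  # empty majority
})

mutate_r <- function(s, p) {
  # independent R-level mutator (substitutions, insertions, deletions each
  # at rate p/3) used as noise source so the test does not lean on rt_mutate
  out <- character(0)
  for (c in strsplit(s, "")[[1L]]) {
    u <- runif(1)
    if (u < p / 3) next
    if (u < 2 * p / 3) c <- sample(setdiff(c("A", "C", "G", "T"), c), 1L)
    out <- c(out, c)
    if (runif(1) < p / 3) out <- c(out, sample(c("A", "C", "G", "T"), 1L))
  }
  paste(out, collapse = "")
}

test_that("consensus of 10 noisy copies is within edit distance 2 of truth", {
  set.seed(2024)
  truth <- rand_seq(200)
  copies <- vapply(1:10, function(i) mutate_r(truth, 0.03), "")
  cons <- consensus_insert(copies)
  # adist is base R's independent edit-distance oracle
  expect_lte(drop(utils::adist(cons, truth)), 2)
})

anchor_world <- function(seed = 31) {
  # two spliced genes with designed mRNAs on a designed chromosome
  set.seed(seed)
  up_mrna <- rand_seq(600)
  down_mrna <- rand_seq(500)
  g1 <- make_designed_gene("UP", up_mrna, 300, "+", 50)
  g2 <- make_designed_gene("DN", down_mrna, 250, "+",
                           50 + nchar(g1$genomic) + 400)
  chrom <- paste0(rand_seq(50), g1$genomic, rand_seq(400), g2$genomic,
                  rand_seq(50))
  genes <- gene_table(gene_id = c("UP", "DN"), chrom = "chrT", strand = "+",
                      start = c(g1$start, g2$start),
                      end = c(g1$end, g2$end),
                      exons = list(g1$exons, g2$exons))
  list(genome = Biostrings::DNAStringSet(c(chrT = chrom)), genes = genes,
       up_mrna = up_mrna, down_mrna = down_mrna)
}

test_that("anchoring recovers an error-free insert exactly", {
  w <- anchor_world()
  insert <- rand_seq(150)
  read <- paste0(w$up_mrna, insert, w$down_mrna)
  anc <- anchor_reads(c(r1 = read), w$genes[1, ], w$genes[2, ], w$genome,
                      read_strands = "+")
  expect_true(anc$anchored)
  expect_equal(anc$insert, insert)
  # reverse-complemented read auto-orients to the same answer
  anc2 <- anchor_reads(c(r1 = readthroughr:::rt_revcomp(read)),
                       w$genes[1, ], w$genes[2, ], w$genome)
  expect_equal(anc2$insert, insert)
  expect_equal(anc2$strand, "-")
})

test_that("a read covering only the upstream gene is excluded", {
  w <- anchor_world(32)
  anc <- anchor_reads(c(r1 = w$up_mrna), w$genes[1, ], w$genes[2, ],
                      w$genome, read_strands = "+")
  expect_false(anc$anchored)
})

test_that("anchoring tolerates 5% errors within the band", {
  w <- anchor_world(33)
  insert <- rand_seq(200)
  set.seed(8)
  for (i in 1:3) {
    read <- mutate_r(paste0(w$up_mrna, insert, w$down_mrna), 0.05)
    anc <- anchor_reads(c(r = read), w$genes[1, ], w$genes[2, ], w$genome,
                        read_strands = "+")
    expect_true(anc$anchored)
    expect_lte(drop(utils::adist(anc$insert, insert)),
               max(20, 0.2 * nchar(insert)))
  }
})

test_that("predict_fate drives the full pipeline on simulated calls", {
  cfg <- sim_config(seed = 91, n_chroms = 1L, genes_per_chrom = 6L,
                    n_readthrough_pairs = 2L, depth = 10, perfect = TRUE)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  idx <- build_index(sim$genome, sim$genes)
  calls <- call_readthroughs(reads$reads, idx)
  fate <- predict_fate(calls, reads$reads, idx, sim$genome)
  expect_true(all(fate$classification %in%
                    c("NMD", "protein_coding", "indeterminate")))
  expect_true(all(fate$n_anchored > 0))
  # spliced-out isoforms keep the upstream stop far from the last junction
  expect_true(all(fate$classification == "NMD"))
  # determinism
  fate2 <- predict_fate(calls, reads$reads, idx, sim$genome)
  expect_equal(fate2, fate)
})
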