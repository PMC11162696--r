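# coordinate conventions, region extraction, BED12 export, rendering

test_that("GTF/BED coordinate conversions are exact inverses", {
  expect_equal(gtf1_to_bed0(100, 200), list(start = 99L, end = 200L))
  expect_equal(gtf1_to_bed0(1, 1), list(start = 0L, end = 1L))
  expect_equal(bed0_to_gtf1(99, 200), list(start = 100L, end = 200L))
  set.seed(6)
  for (i in 1:20) {
    a <- sample(1:1e6, 1L)
    b <- a + sample(0:1e4, 1L)
    expect_equal(bed0_to_gtf1(gtf1_to_bed0(a, b)$start,
                              gtf1_to_bed0(a, b)$end),
                 list(start = a, end = b))
  }
})

region_world <- function(starts, ends, strands = c("+", "+")) {
  set.seed(1)
  chrom <- rand_seq(max(ends) + 100)
  genes <- gene_table(gene_id = c("A", "B"), chrom = "chr1",
                      strand = strands, start = starts, end = ends,
                      exons = list(cbind(starts[1], ends[1]),
                                   cbind(starts[2], ends[2])))
  list(genome = Biostrings::DNAStringSet(c(chr1 = chrom)), genes = genes)
}

test_that("extract_region spans upstream TSS to downstream TTS", {
  w <- region_world(c(100, 400), c(200, 500))
  r <- extract_region(w$genes[1, ], w$genes[2, ], w$genome)
  expect_equal(r$start, 99L)
  expect_equal(r$end, 500L)
  expect_equal(nchar(r$seq), 401L)  # 0-based half-open width

  # minus-strand pair: same genomic window, minus strand
  wm <- region_world(c(100, 400), c(200, 500), strands = c("-", "-"))
  rm_ <- extract_region(wm$genes[2, ], wm$genes[1, ], wm$genome)
  expect_equal(c(rm_$start, rm_$end), c(99L, 500L))
  expect_equal(rm_$strand, "-")

  # overlapping genes: union span
  wo <- region_world(c(100, 150), c(300, 400))
  ro <- extract_region(wo$genes[1, ], wo$genes[2, ], wo$genome)
  expect_equal(c(ro$start, ro$end), c(99L, 400L))
})

bed_world <- function(seed = 14) {
  # two genes with two exons each; fused mRNA should align as 4 blocks
  set.seed(seed)
  g1 <- make_designed_gene("A", rand_seq(700), 350, "+", 60,
                           intron_len = 400, intron_style = "random")
  g2 <- make_designed_gene("B", rand_seq(600), 300, "+",
                           60 + nchar(g1$genomic) + 500, intron_len = 350,
                           intron_style = "random")
  spacer <- sep_seq(500, last_char(g1$genomic), substr(g2$genomic, 1, 1))
  chrom <- paste0(rand_seq(60), g1$genomic, spacer, g2$genomic,
                  rand_seq(60))
  genes <- gene_table(gene_id = c("A", "B"), chrom = "chr1", strand = "+",
                      start = c(g1$start, g2$start),
                      end = c(g1$end, g2$end),
                      exons = list(g1$exons, g2$exons))
  list(genome = Biostrings::DNAStringSet(c(chr1 = chrom)), genes = genes)
}

test_that("an error-free fused mRNA yields a four-block BED12 record", {
  w <- bed_world()
  region <- extract_region(w$genes[1, ], w$genes[2, ], w$genome)
  fused <- paste0(gene_spliced(w$genes[1, ], w$genome),
                  gene_spliced(w$genes[2, ], w$genome))
  bed <- align_and_bed(fused, region, name = "fused")
  expect_equal(bed$blockCount, 4L)
  # blocks equal the exon model (constructed truth)
  ex <- rbind(w$genes$exons[[1L]], w$genes$exons[[2L]])
  sizes <- as.integer(strsplit(bed$blockSizes, ",")[[1L]])
  starts <- as.integer(strsplit(bed$blockStarts, ",")[[1L]])
  expect_equal(sizes, ex[, 2] - ex[, 1] + 1L)
  expect_equal(bed$chromStart + starts + 1L, ex[, 1])
})

test_that("a sequence equal to the region aligns as one full block", {
  w <- bed_world(15)
  region <- extract_region(w$genes[1, ], w$genes[2, ], w$genome)
  bed <- align_and_bed(region$seq, region, name = "whole")
  expect_equal(bed$blockCount, 1L)
  expect_equal(bed$chromStart, region$start)
  expect_equal(bed$chromEnd, region$end)
})

test_that("weak alignments are skipped", {
  w <- bed_world(16)
  region <- extract_region(w$genes[1, ], w$genes[2, ], w$genome)
  set.seed(3)
  expect_warning(out <- align_and_bed(rand_seq(40), region,
                                      score_floor = 100))
  expect_null(out)
  expect_null(align_and_bed("", region))
})

test_that("emitted BED12 re-parses identically through rtracklayer", {
  w <- bed_world(17)
  region <- extract_region(w$genes[1, ], w$genes[2, ], w$genome)
  fused <- paste0(gene_spliced(w$genes[1, ], w$genome),
                  gene_spliced(w$genes[2, ], w$genome))
  bed <- align_and_bed(fused, region, name = "fused")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(bed, f)
  gr <- rtracklayer::import(f, format = "bed")
  blocks <- rtracklayer::blocks(gr)[[1L]]
  sizes <- as.integer(strsplit(bed$blockSizes, ",")[[1L]])
  starts <- as.integer(strsplit(bed$blockStarts, ",")[[1L]])
  expect_equal(IRanges::width(blocks), sizes)
  expect_equal(IRanges::start(blocks), bed$chromStart + starts + 1L)
  # structural invariants
  expect_lte(sum(sizes), region$end - region$start)
  expect_equal(bed$chromStart + starts[length(starts)] +
                 sizes[length(sizes)], bed$chromEnd)
})

test_that("render produces a deterministic non-empty figure", {
  w <- bed_world(18)
  region <- extract_region(w$genes[1, ], w$genes[2, ], w$genome)
  fused <- paste0(gene_spliced(w$genes[1, ], w$genome),
                  gene_spliced(w$genes[2, ], w$genome))
  bed <- align_and_bed(fused, region, name = "fused")
  f <- withr::local_tempfile(fileext = ".pdf")
  render_splice_patterns(bed, w$genes[1, ], w$genes[2, ], f)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 500)
  expect_equal(bed$blockCount, 4L)  # block count stable with the BED
})
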