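# synthetic-data generator: determinism, truth consistency, error model

small_cfg <- function(...) {
  base <- list(seed = 7L, n_chroms = 1L, genes_per_chrom = 6L,
               n_readthrough_pairs = 2L, depth = 5, perfect = TRUE)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$genes, s2$genes)
  expect_identical(as.character(s1$transcripts),
                   as.character(s2$transcripts))
  r1 <- simulate_reads(s1, cfg)
  r2 <- simulate_reads(s2, cfg)
  expect_identical(as.character(r1$reads), as.character(r2$reads))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, r1, d1)
  write_simulation(s2, r2, d2)
  for (f in c("genome.fa", "genes.gtf", "reads.fq", "truth_pairs.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("zero read-through pairs gives an empty truth set", {
  sim <- simulate_genome(small_cfg(n_readthrough_pairs = 0L))
  expect_equal(nrow(sim$truth_pairs), 0L)
  expect_true(all(sim$tx_meta$type == "single"))
})

test_that("read-through cDNAs reconstruct from the annotation", {
  sim <- simulate_genome(small_cfg())
  # oracle: splice each parent out of the written genome + annotation
  for (i in which(sim$tx_meta$type == "readthrough")) {
    up <- sim$genes[match(sim$tx_meta$up_gene_id[i],
                          sim$genes$gene_id), , drop = FALSE]
    down <- sim$genes[match(sim$tx_meta$down_gene_id[i],
                            sim$genes$gene_id), , drop = FALSE]
    want <- paste0(readthroughr:::gene_spliced_seq(up, sim$genome),
                   readthroughr:::gene_spliced_seq(down, sim$genome))
    expect_equal(as.character(sim$transcripts[[sim$tx_meta$tx_id[i]]]),
                 want)
  }
  # and every single-gene transcript equals its spliced gene sequence
  for (i in which(sim$tx_meta$type == "single")) {
    g <- sim$genes[match(sim$tx_meta$up_gene_id[i],
                         sim$genes$gene_id), , drop = FALSE]
    expect_equal(as.character(sim$transcripts[[sim$tx_meta$tx_id[i]]]),
                 readthroughr:::gene_spliced_seq(g, sim$genome))
  }
})

test_that("the written GTF round-trips through parse_annotation", {
  sim <- simulate_genome(small_cfg())
  d <- withr::local_tempdir()
  write_gtf_path <- file.path(d, "genes.gtf")
  readthroughr:::write_gtf(sim$genes, write_gtf_path)
  gt <- parse_annotation(write_gtf_path)
  expect_equal(gt$gene_id, sim$genes$gene_id)
  expect_equal(gt$start, sim$genes$start)
  expect_equal(gt$end, sim$genes$end)
  expect_equal(gt$strand, sim$genes$strand)
  expect_equal(gt$exons, sim$genes$exons, ignore_attr = TRUE)
  expect_equal(gt$cds_start, sim$genes$cds_start)
  expect_equal(gt$cds_end, sim$genes$cds_end)
})

test_that("perfect reads are exact substrings at their truth coordinates", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, cfg)
  txs <- as.character(sim$transcripts)
  tr <- rd$truth_reads
  for (i in sample(nrow(tr), 25L)) {
    want <- substr(txs[[tr$tx_id[i]]], tr$tx_start[i], tr$tx_end[i])
    if (tr$strand[i] == "-") want <- readthroughr:::rt_revcomp(want)
    expect_identical(as.character(rd$reads[[tr$read_id[i]]]), want)
  }
})

test_that("per-read coverage respects the minimum fraction", {
  cfg <- small_cfg(min_coverage_frac = 0.95)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, cfg)
  L <- setNames(sim$tx_meta$length, sim$tx_meta$tx_id)
  expect_true(all(rd$truth_reads$length >=
                    floor(0.95 * L[rd$truth_reads$tx_id])))
})

test_that("depth accounting stays within 10% of the target", {
  cfg <- small_cfg(depth = 20)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, cfg)
  bases <- tapply(rd$truth_reads$length, rd$truth_reads$tx_id, sum)
  L <- setNames(sim$tx_meta$length, sim$tx_meta$tx_id)
  ratio <- bases / (L[names(bases)] * 20)
  expect_true(all(ratio >= 0.9 & ratio <= 1.1))
})

test_that("substitution counts follow the stated binomial rate", {
  cfg <- small_cfg(perfect = FALSE,
                   error_rates = c(sub = 0.03, ins = 0, del = 0),
                   depth = 10)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, cfg)
  txs <- as.character(sim$transcripts)
  tr <- rd$truth_reads
  mism <- 0L
  total <- 0L
  for (i in seq_len(nrow(tr))) {
    want <- substr(txs[[tr$tx_id[i]]], tr$tx_start[i], tr$tx_end[i])
    if (tr$strand[i] == "-") want <- readthroughr:::rt_revcomp(want)
    got <- as.character(rd$reads[[tr$read_id[i]]])
    expect_equal(nchar(got), nchar(want))  # no indels in this setting
    a <- strsplit(got, "")[[1L]]
    b <- strsplit(want, "")[[1L]]
    mism <- mism + sum(a != b)
    total <- total + length(a)
  }
  # substituted bases change with prob 1 (never resampled identically)
  expected <- 0.03 * total
  sd3 <- 3 * sqrt(total * 0.03 * 0.97)
  expect_gt(mism, expected - sd3)
  expect_lt(mism, expected + sd3)
})

test_that("retained-insert isoforms carry the intergenic sequence", {
  sim <- simulate_genome(small_cfg(insert_mode = "retained"))
  i <- which(sim$tx_meta$type == "readthrough")[1L]
  up <- sim$genes[match(sim$tx_meta$up_gene_id[i],
                        sim$genes$gene_id), , drop = FALSE]
  down <- sim$genes[match(sim$tx_meta$down_gene_id[i],
                          sim$genes$gene_id), , drop = FALSE]
  L <- nchar(as.character(sim$transcripts[[sim$tx_meta$tx_id[i]]]))
  gap <- abs(max(up$start, down$start) - min(up$end, down$end)) - 1L
  up_len <- sum(up$exons[[1]][, 2] - up$exons[[1]][, 1] + 1L)
  down_len <- sum(down$exons[[1]][, 2] - down$exons[[1]][, 1] + 1L)
  expect_equal(L, up_len + gap + down_len)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_chroms = 1L, genes_per_chrom = 4L,
                          n_readthrough_pairs = 5L), "too many")
  expect_error(sim_config(min_coverage_frac = 0))
})
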