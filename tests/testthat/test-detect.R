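# two-stage detection: screening, confirmation, aggregation, metrics

detect_world <- function(seed = 42, strands = c("+", "+")) {
  w <- two_gene_world(seed, strands = strands)
  w$idx <- build_index(w$genome, w$genes, noisy_params())
  w
}

test_that("screening finds the right region and gene hit pattern", {
  w <- detect_world(61)
  # read copied from one gene: its IAR is the (single) candidate
  r1 <- substr(w$sense[["GA"]], 101, 600)
  cands <- screen_read(r1, w$idx)
  expect_length(cands, 1L)
  expect_equal(cands[[1L]]$iar, 1L)
  expect_gt(cands[[1L]]$per_gene_hits[1L], 0L)
  expect_equal(cands[[1L]]$per_gene_hits[2L], 0L)

  # unrelated sequence: no candidates
  set.seed(999)
  expect_length(screen_read(rand_seq(400), w$idx), 0L)

  # spanning read: both genes hit within one candidate
  r2 <- paste0(substr(w$sense[["GA"]], 401, 800),
               substr(w$sense[["GB"]], 1, 400))
  cands2 <- screen_read(r2, w$idx)
  expect_length(cands2, 1L)
  expect_true(all(cands2[[1L]]$per_gene_hits > 0L))
})

test_that("confirmation requires two adjacent genes in the right order", {
  w <- detect_world(62)
  spanning <- paste0(substr(w$sense[["GA"]], 401, 800),
                     substr(w$sense[["GB"]], 1, 400))
  hit <- confirm_readthrough(spanning, w$idx)
  expect_equal(hit$up_gene_id, "GA")
  expect_equal(hit$down_gene_id, "GB")
  expect_true(hit$transition > 300 && hit$transition < 500)

  # single-gene read, even with many hits, is never confirmed
  expect_null(confirm_readthrough(w$sense[["GA"]], w$idx))
  # wrong order (B prefix then A suffix) fails the order check
  wrong <- paste0(substr(w$sense[["GB"]], 1, 400),
                  substr(w$sense[["GA"]], 401, 800))
  expect_null(confirm_readthrough(wrong, w$idx))
})

test_that("reverse-complemented spanning reads are confirmed identically", {
  w <- detect_world(63)
  spanning <- paste0(substr(w$sense[["GA"]], 401, 800),
                     substr(w$sense[["GB"]], 1, 400))
  hit <- confirm_readthrough(readthroughr:::rt_revcomp(spanning), w$idx)
  expect_equal(hit$up_gene_id, "GA")
  expect_equal(hit$read_strand, "-")
})

test_that("minus-strand pairs use transcription order for upstream", {
  w <- detect_world(64, strands = c("-", "-"))
  # upstream is the genomically-right gene (GB); fused cDNA in sense order
  spanning <- paste0(substr(w$sense[["GB"]], 401, 800),
                     substr(w$sense[["GA"]], 1, 400))
  hit <- confirm_readthrough(spanning, w$idx)
  expect_equal(hit$up_gene_id, "GB")
  expect_equal(hit$down_gene_id, "GA")
  expect_equal(hit$gene_strand, "-")
})

test_that("opposite-strand neighbours are rejected unless allowed", {
  w <- detect_world(65, strands = c("+", "-"))
  spanning <- paste0(substr(w$sense[["GA"]], 401, 800),
                     substr(w$sense[["GB"]], 1, 400))
  expect_null(confirm_readthrough(spanning, w$idx))
  hit <- confirm_readthrough(spanning, w$idx, same_strand = FALSE)
  expect_false(is.null(hit))
})

make_read_set <- function(w, n_span = 4, n_single = 6) {
  spanning <- paste0(substr(w$sense[["GA"]], 401, 800),
                     substr(w$sense[["GB"]], 1, 400))
  reads <- c(rep(spanning, n_span),
             rep(substr(w$sense[["GA"]], 1, 700), n_single))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  Biostrings::DNAStringSet(reads)
}

test_that("call_readthroughs aggregates, filters and sorts", {
  w <- detect_world(66)
  reads <- make_read_set(w)
  calls <- call_readthroughs(reads, w$idx, min_support = 1)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$upstream_gene_id, "GA")
  expect_equal(calls$n_supporting_reads, 4L)
  expect_equal(strsplit(calls$read_ids, ",")[[1L]], sprintf("r%02d", 1:4))

  # min_support above the support count empties the output
  expect_equal(nrow(call_readthroughs(reads, w$idx, min_support = 5)), 0L)

  # raising min_support never adds calls (anti-monotone filter)
  sizes <- vapply(0:5, function(m)
    nrow(call_readthroughs(reads, w$idx, min_support = m)), 1L)
  expect_true(all(diff(sizes) <= 0))

  # shuffling the input changes nothing
  set.seed(4)
  shuffled <- reads[sample(length(reads))]
  calls2 <- call_readthroughs(shuffled, w$idx, min_support = 1)
  expect_equal(calls2, calls, ignore_attr = TRUE)
})

test_that("screening at default thresholds loses no confirmable pair", {
  w <- detect_world(67)
  reads <- make_read_set(w)
  strict <- call_readthroughs(reads, w$idx, screen_min_hits = 4)
  loose <- call_readthroughs(reads, w$idx, screen_min_hits = 0)
  expect_equal(strict$upstream_gene_id, loose$upstream_gene_id)
  expect_equal(strict$n_supporting_reads, loose$n_supporting_reads)
})

test_that("compute_metrics implements the formulas", {
  m <- compute_metrics(
    data.frame(upstream_gene_id = "A", downstream_gene_id = "B"),
    data.frame(up_gene_id = c("A", "C"), down_gene_id = c("B", "D")))
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 1)

  truth <- data.frame(up_gene_id = c("A", "X"), down_gene_id = c("B", "Y"))
  calls <- data.frame(upstream_gene_id = c("A", "X"),
                      downstream_gene_id = c("B", "Y"))
  m2 <- compute_metrics(calls, truth)
  expect_equal(c(m2$recall, m2$precision, m2$f1), c(1, 1, 1))

  m3 <- compute_metrics(
    data.frame(upstream_gene_id = c("A", "X"),
               downstream_gene_id = c("B", "Y")),
    data.frame(up_gene_id = "A", down_gene_id = "B"))
  expect_equal(m3$precision, 0.5)

  # order matters: a swapped pair is not a true positive
  m4 <- compute_metrics(
    data.frame(upstream_gene_id = "B", downstream_gene_id = "A"),
    data.frame(up_gene_id = "A", down_gene_id = "B"))
  expect_equal(m4$tp, 0L)

  # empty truth: recall undefined
  m5 <- compute_metrics(
    data.frame(upstream_gene_id = "A", downstream_gene_id = "B"),
    data.frame(up_gene_id = character(0), down_gene_id = character(0)))
  expect_true(is.na(m5$recall))
})
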