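# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random separator whose boundary characters avoid the flanking blocks:
# without this, splice-boundary micro-homology makes gap placement in
# alignments ambiguous by a base or two, which breaks exact block oracles
sep_seq <- function(n, prev_char, next_char) {
  s <- strsplit(rand_seq(n), "")[[1L]]
  s[1L] <- sample(setdiff(c("A", "C", "G", "T"), next_char), 1L)
  s[n] <- sample(setdiff(c("A", "C", "G", "T"), prev_char), 1L)
  paste(s, collapse = "")
}

last_char <- function(s) substr(s, nchar(s), nchar(s))

# 16-digit hex word for a non-negative double below 2^53 (sprintf's %x only
# accepts integer-typed input, which caps at 2^31)
hex53 <- function(x) {
  digits <- c(as.character(0:9), letters[1:6])
  vapply(x, function(v) {
    d <- integer(16)
    for (i in 16:1) {
      r <- v %% 16
      d[i] <- r
      v <- (v - r) / 16
    }
    paste(digits[d + 1L], collapse = "")
  }, "", USE.NAMES = FALSE)
}

gene_spliced <- function(gene, genome) {
  readthroughr:::gene_spliced_seq(gene, genome)
}

# random non-overlapping gene layout across chromosomes, for partition
# property tests
random_gene_layout <- function(n, n_chroms = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sort(sample(paste0("chr", seq_len(n_chroms)), n, replace = TRUE))
  rows <- lapply(seq_len(n), function(i) NULL)
  pos <- setNames(rep(1L, n_chroms), paste0("chr", seq_len(n_chroms)))
  starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    gap <- sample(100:200000, 1L)
    len <- sample(500:5000, 1L)
    starts[i] <- pos[[chrom[i]]] + gap
    ends[i] <- starts[i] + len - 1L
    pos[[chrom[i]]] <- ends[i]
  }
  gene_table(gene_id = sprintf("g%04d", seq_len(n)), chrom = chrom,
             strand = sample(c("+", "-"), n, replace = TRUE),
             start = starts, end = ends,
             exons = lapply(seq_len(n), function(i) cbind(starts[i], ends[i])))
}

# independent gap-scan oracle for the IAR rule
oracle_partition <- function(genes, thr) {
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  out <- list()
  cur <- 1L
  for (i in seq_len(nrow(genes))[-1L]) {
    gap <- genes$start[i] - genes$end[i - 1L]
    if (genes$chrom[i] != genes$chrom[i - 1L] || gap > thr) {
      out[[length(out) + 1L]] <- genes$gene_id[cur:(i - 1L)]
      cur <- i
    }
  }
  out[[length(out) + 1L]] <- genes$gene_id[cur:nrow(genes)]
  out
}

# brute-force sketch oracle: hash every k-mer of every window, take the
# leftmost argmin (hex strings order like the underlying 64-bit values)
oracle_sketch <- function(seq, k, s, st) {
  empty <- data.frame(hash = character(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (L < k) return(empty)
  if (L < s) {
    starts <- 0L
    w <- L
  } else {
    starts <- seq.int(0L, L - s, by = st)
    if (max(starts) + s < L) starts <- c(starts, L - s)
    w <- s
  }
  np <- L - k + 1L
  kh <- kmer_hash(substring(seq, seq_len(np), seq_len(np) + k - 1L))
  rows <- list()
  for (x in starts) {
    idx <- (x + 1L):(x + w - k + 1L)
    h <- kh[idx]
    ok <- !is.na(h)
    if (!any(ok)) next
    j <- which(ok)[which(h[ok] == min(h[ok]))[1L]]
    rows[[length(rows) + 1L]] <- data.frame(hash = h[j], offset = idx[j] - 1L,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$offset, df$hash), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# deterministic one-chromosome world with two single-exon genes, for the
# detection unit tests; genes are long enough to sketch densely
two_gene_world <- function(seed = 42, glen = 800, gap = 300,
                           strands = c("+", "+")) {
  set.seed(seed)
  lead <- rand_seq(200)
  g1 <- rand_seq(glen)
  g2 <- rand_seq(glen)
  mid <- rand_seq(gap)
  chrom <- paste0(lead, g1, mid, g2, rand_seq(200))
  s1 <- 200L + 1L
  s2 <- 200L + glen + gap + 1L
  genes <- gene_table(
    gene_id = c("GA", "GB"), chrom = "chr1", strand = strands,
    start = c(s1, s2), end = c(s1 + glen - 1L, s2 + glen - 1L),
    exons = list(cbind(s1, s1 + glen - 1L), cbind(s2, s2 + glen - 1L)))
  sense1 <- if (strands[1L] == "+") g1 else readthroughr:::rt_revcomp(g1)
  sense2 <- if (strands[2L] == "+") g2 else readthroughr:::rt_revcomp(g2)
  list(genome = Biostrings::DNAStringSet(c(chr1 = chrom)), genes = genes,
       sense = c(GA = sense1, GB = sense2))
}

noisy_params <- function() sketch_params(preset = "noisy")

# designed two-gene fate world: exon sequences are supplied as mRNA slices
# so stop-codon positions are fully controlled. Filler sequence is A-free,
# hence stop-free in every frame.
gc_filler <- function(n) {
  paste(rep_len(c("G", "C", "G", "G", "C", "C"), n), collapse = "")
}

# Build a plus- or minus-strand two-exon gene from its designed mRNA.
# Returns the genomic sequence chunk and a gene_table row builder.
make_designed_gene <- function(id, mrna, exon1_len, strand, chrom_offset,
                               intron_len = 50, cds = NULL,
                               intron_style = c("gc", "random")) {
  intron_style <- match.arg(intron_style)
  stopifnot(nchar(mrna) > exon1_len)
  chrom_offset <- as.integer(chrom_offset)
  intron_len <- as.integer(intron_len)
  exon1_len <- as.integer(exon1_len)
  e1 <- substr(mrna, 1L, exon1_len)
  e2 <- substr(mrna, exon1_len + 1L, nchar(mrna))
  intron <- if (intron_style == "gc") gc_filler(intron_len) else
    sep_seq(intron_len, last_char(e1), substr(e2, 1L, 1L))
  sense_genomic <- paste0(e1, intron, e2)
  Lg <- nchar(sense_genomic)
  S <- chrom_offset + 1L
  genomic <- if (strand == "+") sense_genomic else
    readthroughr:::rt_revcomp(sense_genomic)
  # sense intervals of the two exons
  a <- c(1L, exon1_len + intron_len + 1L)
  b <- c(exon1_len, Lg)
  to_g <- function(p) if (strand == "+") S + p - 1L else S + Lg - p
  exons <- t(vapply(1:2, function(i) sort(c(to_g(a[i]), to_g(b[i]))),
                    c(1L, 1L)))
  cds_g <- c(NA_integer_, NA_integer_)
  if (!is.null(cds)) {
    # cds given in mRNA coordinates; map through the exon model
    map1 <- function(p) {
      if (p <= exon1_len) to_g(p) else to_g(p + intron_len)
    }
    cds_g <- sort(c(map1(cds[1L]), map1(cds[2L])))
  }
  list(genomic = genomic, start = S, end = S + Lg - 1L,
       exons = cbind(start = exons[, 1L], end = exons[, 2L]),
       cds_start = cds_g[1L], cds_end = cds_g[2L], id = id, strand = strand)
}

# assemble a fate test world: upstream gene (ATG at mRNA pos 11, stop-free
# CDS to the gene end), downstream gene with supplied mRNA, plus strand or
# minus strand as requested
fate_world <- function(down_mrna, strand = "+", up_len = 120,
                       up_exon1 = 60, down_exon1 = 60) {
  up_mrna <- paste0(gc_filler(10), "ATG", gc_filler(up_len - 13L))
  g1 <- make_designed_gene("UP", up_mrna, up_exon1, strand, 100L,
                           cds = c(11L, up_len))
  g2 <- make_designed_gene("DN", down_mrna, down_exon1, strand,
                           100L + nchar(g1$genomic) + 200L)
  chrom <- paste0(gc_filler(100), g1$genomic, gc_filler(200), g2$genomic,
                  gc_filler(50))
  ord <- if (strand == "+") list(g1, g2) else list(g2, g1)
  up <- if (strand == "+") g1 else NULL
  genes <- gene_table(
    gene_id = c(g1$id, g2$id), chrom = "chrT", strand = strand,
    start = c(g1$start, g2$start), end = c(g1$end, g2$end),
    exons = list(g1$exons, g2$exons),
    cds_start = c(g1$cds_start, g2$cds_start),
    cds_end = c(g1$cds_end, g2$cds_end))
  # transcription order: on minus strand the genomically-right gene (DN
  # chunk) would be upstream, so for minus tests we instead swap roles via
  # coordinates: callers always use UP as upstream and DN as downstream,
  # which on the minus strand means UP must sit genomically right.
  list(genome = Biostrings::DNAStringSet(c(chrT = chrom)), genes = genes,
       up_mrna = up_mrna, down_mrna = down_mrna)
}
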