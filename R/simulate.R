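#' Configuration for the synthetic benchmark
#'
#' Describes the stated world of the simulated benchmark: a toy genome of
#' multi-exon coding genes with realistic intergenic gaps, a set of
#' adjacent same-strand gene pairs expressing a read-through isoform at the
#' same level as the single-gene transcripts, and long reads sampled to a
#' target fold-coverage with a minimum per-read length-coverage fraction,
#' optionally with i.i.d. substitution/insertion/deletion errors.
#'
#' @param seed integer seed; every random choice in the generator derives
#'   from it.
#' @param n_chroms,genes_per_chrom genome layout.
#' @param n_readthrough_pairs number of adjacent gene pairs given a
#'   read-through isoform (pairs are disjoint and same-strand).
#' @param depth target fold-coverage per transcript (reads are drawn until
#'   sampled bases reach `depth * length`).
#' @param min_coverage_frac minimum fraction of its transcript a read must
#'   cover; per-read fractions are uniform on `[min_coverage_frac, 1]` and
#'   reads are 5'- or 3'-anchored with equal probability.
#' @param error_rates named numeric vector `c(sub=, ins=, del=)` of per-base
#'   probabilities; defaults approximate ONT-class error (2/3/3 percent).
#' @param perfect when `TRUE`, reads are exact substrings (error-free mode).
#' @param insert_mode `"spliced_out"` (read-through cDNA is the clean
#'   concatenation of the two spliced parents) or `"retained"` (the
#'   intergenic sequence is kept in the isoform).
#' @param exon_count_range,exon_len_range,intron_len_range,gap_range,
#'   big_gap_prob,big_gap_range gene-structure and layout distributions
#'   (bp). Occasional `big_gap` draws exceed the default IAR threshold so
#'   partitioning is exercised.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, genes_per_chrom = 20L,
                       n_readthrough_pairs = 10L, depth = 100,
                       min_coverage_frac = 0.9,
                       error_rates = c(sub = 0.02, ins = 0.03, del = 0.03),
                       perfect = FALSE,
                       insert_mode = c("spliced_out", "retained"),
                       exon_count_range = c(2L, 5L),
                       exon_len_range = c(150L, 450L),
                       intron_len_range = c(300L, 1500L),
                       gap_range = c(2000L, 20000L),
                       big_gap_prob = 0.1,
                       big_gap_range = c(150000L, 250000L)) {
  insert_mode <- match.arg(insert_mode)
  stopifnot(depth > 0, min_coverage_frac > 0, min_coverage_frac <= 1,
            all(error_rates >= 0), all(error_rates <= 1),
            sum(error_rates[c("sub", "del")]) <= 1)
  n_slots <- n_chroms * length(seq.int(1L, genes_per_chrom - 1L, by = 2L))
  if (n_readthrough_pairs > n_slots)
    stop("too many read-through pairs for this layout")
  cfg <- as.list(environment())
  cfg$n_slots <- NULL
  cfg$cfg <- NULL
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# codons excluding the three stops
non_stop_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# draw one gene: sense mRNA with a clean ORF, exon split, intron lengths
draw_gene_model <- function(cfg) {
  n_ex <- sample(cfg$exon_count_range[1L]:cfg$exon_count_range[2L], 1L)
  ex_lens <- sample(cfg$exon_len_range[1L]:cfg$exon_len_range[2L], n_ex,
                    replace = TRUE)
  total <- sum(ex_lens)
  utr5 <- sample(30:80, 1L)
  utr3 <- sample(40:90, 1L)
  cds_len <- total - utr5 - utr3
  cds_len <- cds_len - cds_len %% 3L
  stopifnot(cds_len >= 9L)
  body <- paste(sample(non_stop_codons(), (cds_len - 6L) / 3L,
                       replace = TRUE), collapse = "")
  mrna <- paste0(rand_dna(utr5), "ATG", body,
                 sample(c("TAA", "TAG", "TGA"), 1L),
                 rand_dna(total - utr5 - cds_len))
  introns <- if (n_ex > 1L)
    sample(cfg$intron_len_range[1L]:cfg$intron_len_range[2L], n_ex - 1L,
           replace = TRUE) else integer(0)
  cuts <- cumsum(ex_lens)
  exon_seqs <- substring(mrna, c(1L, cuts[-n_ex] + 1L), cuts)
  list(mrna = mrna, exon_lens = ex_lens, introns = introns,
       exon_seqs = exon_seqs, utr5 = utr5, cds_len = cds_len)
}

#' Generate a toy genome, annotation and truth transcript set
#'
#' Lays out random multi-exon coding genes with configurable intergenic
#' gaps, assigns every gene a spliced transcript, and gives each selected
#' adjacent same-strand pair a read-through isoform (upstream spliced exons
#' + optional intergenic insert + downstream spliced exons). Normal and
#' read-through transcripts get equal expression. Rerunning with the same
#' config is byte-identical.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `genes` (`gene_table`),
#'   `transcripts` (named `DNAStringSet`), `tx_meta`, and `truth_pairs`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  cfg <- config
  n_total <- cfg$n_chroms * cfg$genes_per_chrom

  # choose disjoint adjacent pair positions per chromosome up front
  pair_slots <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
    cbind(chrom = ci, left = seq(1L, cfg$genes_per_chrom - 1L, by = 2L))
  }))
  sel <- sample(nrow(pair_slots), cfg$n_readthrough_pairs)
  pairs <- pair_slots[sel, , drop = FALSE]

  strands <- matrix(sample(c("+", "-"), n_total, replace = TRUE),
                    nrow = cfg$n_chroms, byrow = TRUE)
  for (p in seq_len(nrow(pairs))) {
    ci <- pairs[p, "chrom"]; li <- pairs[p, "left"]
    strands[ci, li + 1L] <- strands[ci, li]  # pairs share a strand
  }

  chrom_seqs <- character(cfg$n_chroms)
  rows <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    parts <- character(0)
    pos <- 0L  # bases emitted so far on this chromosome
    pair_left_here <- pairs[pairs[, "chrom"] == ci, "left"]
    for (k in seq_len(cfg$genes_per_chrom)) {
      gi <- gi + 1L
      # a gap closing a read-through pair is never a desert
      big <- !(k - 1L) %in% pair_left_here && k > 1L &&
        runif(1L) < cfg$big_gap_prob
      gap <- if (big)
        sample(cfg$big_gap_range[1L]:cfg$big_gap_range[2L], 1L)
      else sample(cfg$gap_range[1L]:cfg$gap_range[2L], 1L)
      gm <- draw_gene_model(cfg)
      strand <- strands[ci, k]
      sense <- paste(as.vector(rbind(
        c(gm$exon_seqs, ""),
        c(vapply(gm$introns, rand_dna, ""), "", ""))[seq_len(
          2L * length(gm$exon_seqs) - 1L)]), collapse = "")
      Lg <- nchar(sense)
      S <- pos + gap + 1L
      genomic <- if (strand == "+") sense else rt_revcomp(sense)
      parts <- c(parts, rand_dna(gap), genomic)
      pos <- S + Lg - 1L
      # sense-coordinate exon intervals
      bnd <- cumsum(as.vector(rbind(gm$exon_lens,
                                    c(gm$introns, 0L)))[seq_len(
                                      2L * length(gm$exon_lens) - 1L)])
      a <- c(1L, bnd[seq_along(bnd) %% 2L == 0L] + 1L)
      b <- bnd[seq_along(bnd) %% 2L == 1L]
      to_genomic <- function(p_) if (strand == "+") S + p_ - 1L else S + Lg - p_
      ex <- t(vapply(seq_along(gm$exon_lens), function(e_)
        sort(c(to_genomic(a[e_]), to_genomic(b[e_]))), c(1L, 1L)))
      cds_sense <- c(gm$utr5 + 1L, gm$utr5 + gm$cds_len)
      cds_sp <- spliced_to_sense(a, b, cds_sense)
      cds_g <- sort(c(to_genomic(cds_sp[1L]), to_genomic(cds_sp[2L])))
      rows[[gi]] <- list(
        gene_id = sprintf("G%03d", gi), chrom = paste0("chr", ci),
        strand = strand, start = S, end = S + Lg - 1L,
        exons = cbind(start = ex[, 1L], end = ex[, 2L]),
        cds_start = cds_g[1L], cds_end = cds_g[2L], mrna = gm$mrna)
    }
    parts <- c(parts, rand_dna(sample(cfg$gap_range[1L]:cfg$gap_range[2L],
                                      1L)))
    chrom_seqs[ci] <- paste(parts, collapse = "")
  }

  genes <- gene_table(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, function(x) x$start, 1L),
    end = vapply(rows, function(x) x$end, 1L),
    exons = lapply(rows, `[[`, "exons"),
    cds_start = vapply(rows, function(x) x$cds_start, 1L),
    cds_end = vapply(rows, function(x) x$cds_end, 1L))

  genome <- Biostrings::DNAStringSet(setNames(chrom_seqs,
                                              paste0("chr",
                                                     seq_len(cfg$n_chroms))))

  mrnas <- setNames(vapply(rows, `[[`, "", "mrna"),
                    vapply(rows, `[[`, "", "gene_id"))
  tx <- as.list(mrnas)
  meta <- data.frame(tx_id = names(mrnas), type = "single",
                     up_gene_id = names(mrnas),
                     down_gene_id = NA_character_,
                     stringsAsFactors = FALSE)

  truth <- NULL
  for (p in seq_len(nrow(pairs))) {
    ci <- pairs[p, "chrom"]; li <- pairs[p, "left"]
    iL <- (ci - 1L) * cfg$genes_per_chrom + li
    iR <- iL + 1L
    strand <- rows[[iL]]$strand
    up_i <- if (strand == "+") iL else iR    # transcription order
    down_i <- if (strand == "+") iR else iL
    insert <- ""
    if (cfg$insert_mode == "retained") {
      ig <- as.character(Biostrings::subseq(
        genome[[rows[[iL]]$chrom]], rows[[iL]]$end + 1L,
        rows[[iR]]$start - 1L))
      insert <- if (strand == "+") ig else rt_revcomp(ig)
    }
    id <- paste0("RT_", rows[[up_i]]$gene_id, "_", rows[[down_i]]$gene_id)
    tx[[id]] <- paste0(rows[[up_i]]$mrna, insert, rows[[down_i]]$mrna)
    meta <- rbind(meta, data.frame(
      tx_id = id, type = "readthrough",
      up_gene_id = rows[[up_i]]$gene_id,
      down_gene_id = rows[[down_i]]$gene_id, stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      up_gene_id = rows[[up_i]]$gene_id,
      down_gene_id = rows[[down_i]]$gene_id,
      chrom = rows[[iL]]$chrom, strand = strand, stringsAsFactors = FALSE))
  }
  if (is.null(truth))
    truth <- data.frame(up_gene_id = character(0),
                        down_gene_id = character(0), chrom = character(0),
                        strand = character(0), stringsAsFactors = FALSE)
  meta$length <- nchar(unlist(tx[meta$tx_id], use.names = FALSE))

  list(genome = genome, genes = genes,
       transcripts = Biostrings::DNAStringSet(unlist(tx)),
       tx_meta = meta, truth_pairs = truth, config = cfg)
}

# map a spliced (mRNA) interval to sense-genomic coordinates given exon
# sense intervals [a, b]
spliced_to_sense <- function(a, b, interval) {
  lens <- b - a + 1L
  cum <- cumsum(c(0L, lens))
  mapp <- function(p) {
    e <- max(which(cum < p))
    a[e] + (p - cum[e]) - 1L
  }
  c(mapp(interval[1L]), mapp(interval[2L]))
}

#' Simulate long reads with truth labels
#'
#' Per transcript, reads are drawn until the sampled bases reach
#' `depth * length`. Each read covers a contiguous fraction drawn uniformly
#' on `[min_coverage_frac, 1]`, anchored at the 5' or 3' end with equal
#' probability, is reverse-complemented half of the time, and (unless
#' `perfect`) receives i.i.d. per-base substitutions, insertions and
#' deletions. Truth coordinates are recorded before error injection.
#'
#' @param sim output of [simulate_genome()].
#' @param config a [sim_config()]; defaults to the one stored in `sim`.
#' @return list with `reads` (named `DNAStringSet`) and `truth_reads`.
#' @export
simulate_reads <- function(sim, config = sim$config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  txs <- as.character(sim$transcripts)
  seqs <- character(0)
  truth <- list()
  ridx <- 0L
  for (t in seq_along(txs)) {
    L <- nchar(txs[t])
    target <- cfg$depth * L
    got <- 0
    while (got < target) {
      ridx <- ridx + 1L
      frac <- runif(1L, cfg$min_coverage_frac, 1)
      len <- max(50L, round(frac * L))
      from5 <- runif(1L) < 0.5
      start <- if (from5) 1L else L - len + 1L
      s <- substr(txs[t], start, start + len - 1L)
      strand <- if (runif(1L) < 0.5) "+" else "-"
      if (strand == "-") s <- rt_revcomp(s)
      seqs[ridx] <- s
      truth[[ridx]] <- data.frame(
        read_id = sprintf("read%06d", ridx), tx_id = names(txs)[t],
        tx_start = start, tx_end = start + len - 1L, strand = strand,
        length = len, stringsAsFactors = FALSE)
      got <- got + len
    }
  }
  if (!cfg$perfect) {
    seqs <- as.character(rt_mutate(seqs, cfg$error_rates[["sub"]],
                                   cfg$error_rates[["ins"]],
                                   cfg$error_rates[["del"]]))
  }
  truth <- do.call(rbind, truth)
  names(seqs) <- truth$read_id
  list(reads = Biostrings::DNAStringSet(seqs), truth_reads = truth)
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `genes.gtf`, `reads.fq`, `truth_pairs.tsv` and
#' `truth_reads.tsv` under `out_dir`.
#'
#' @param sim output of [simulate_genome()].
#' @param reads output of [simulate_reads()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, reads, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_gtf(sim$genes, file.path(out_dir, "genes.gtf"))
  write_fastq(reads$reads, file.path(out_dir, "reads.fq"))
  utils::write.table(sim$truth_pairs, file.path(out_dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(reads$truth_reads,
                     file.path(out_dir, "truth_reads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
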