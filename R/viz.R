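# Splice-pattern export: region extraction, splice-tolerant alignment to
# BED12, and a minimal exon-block figure.
#
# All GTF (1-based inclusive) <-> BED (0-based half-open) conversions go
# through the two functions below so the convention lives in one place.

#' Coordinate conversions between GTF and BED conventions
#'
#' @param start,end 1-based inclusive interval (GTF convention).
#' @return `gtf1_to_bed0`: list with 0-based half-open `start`, `end`;
#'   `bed0_to_gtf1`: list with 1-based inclusive `start`, `end`.
#' @examples
#' gtf1_to_bed0(100, 200)  # start 99, end 200
#' @export
gtf1_to_bed0 <- function(start, end) list(start = start - 1L, end = end)

#' @rdname gtf1_to_bed0
#' @export
bed0_to_gtf1 <- function(start, end) list(start = start + 1L, end = end)

#' Extract the upstream-TSS to downstream-TTS window of a call
#'
#' @param up_gene,down_gene one-row `gene_table` slices (same chromosome).
#' @param genome `DNAStringSet` or FASTA path.
#' @return list with `chrom`, 0-based half-open `start`/`end`, `strand` and
#'   the region `seq`. Out-of-bounds windows are clamped with a warning.
#' @export
extract_region <- function(up_gene, down_gene, genome) {
  if (up_gene$chrom != down_gene$chrom)
    stop("genes of one read-through must share a chromosome")
  genome <- load_genome(genome)
  chrom_seq <- genome_chrom(genome, up_gene$chrom)
  lo <- min(up_gene$start, down_gene$start)
  hi <- max(up_gene$end, down_gene$end)
  if (lo < 1L || hi > length(chrom_seq)) {
    warning("region clamped to chromosome bounds")
    lo <- max(1L, lo)
    hi <- min(length(chrom_seq), hi)
  }
  b <- gtf1_to_bed0(lo, hi)
  list(chrom = up_gene$chrom, start = b$start, end = b$end,
       strand = up_gene$strand,
       seq = as.character(Biostrings::subseq(chrom_seq, lo, hi)))
}

#' Align a sequence to a region and emit a BED12 record
#'
#' Local alignment with cheap gap extension so that multi-kb intron gaps are
#' affordable; region gaps of at least `min_intron` bp are collapsed into
#' introns, producing the BED12 block structure. thickStart/thickEnd equal
#' chromStart/chromEnd.
#'
#' @param seq query sequence (a read, consensus, or fused mRNA).
#' @param region list from [extract_region()].
#' @param name BED name field.
#' @param strand BED strand field.
#' @param min_intron minimum region-gap length collapsed to an intron.
#' @param score_floor minimum alignment score; weaker alignments are skipped
#'   (returns `NULL` with a warning).
#' @return one-row data.frame with the 12 standard BED columns, or `NULL`.
#' @export
align_and_bed <- function(seq, region, name = "aln", strand = "+",
                          min_intron = 30, score_floor = 30) {
  if (!nzchar(seq)) return(NULL)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(seq)),
    subject = Biostrings::DNAString(toupper(region$seq)),
    type = "local", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 0.05)
  if (Biostrings::score(pa) < score_floor) {
    warning("alignment below score floor; record skipped")
    return(NULL)
  }
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  sub_start <- IRanges::start(Biostrings::subject(pa))

  # walk columns; a run of >= min_intron subject-consuming pattern gaps
  # splits blocks
  blocks <- list()
  cur_start <- NA_integer_
  cur_end <- NA_integer_
  gap_run <- 0L
  spos <- sub_start - 1L  # last consumed subject position
  for (t in seq_along(as_)) {
    if (as_[t] == "-") next  # insertion in the read: no region advance
    spos <- spos + 1L
    if (ap[t] == "-") {
      gap_run <- gap_run + 1L
    } else {
      if (!is.na(cur_start) && gap_run >= min_intron) {
        blocks[[length(blocks) + 1L]] <- c(cur_start, cur_end)
        cur_start <- NA_integer_
      }
      gap_run <- 0L
      if (is.na(cur_start)) cur_start <- spos
      cur_end <- spos
    }
  }
  if (!is.na(cur_start)) blocks[[length(blocks) + 1L]] <- c(cur_start, cur_end)
  if (length(blocks) == 0L) return(NULL)

  bm <- do.call(rbind, blocks)  # 1-based positions within the region
  chrom_start <- region$start + bm[1L, 1L] - 1L  # 0-based
  chrom_end <- region$start + bm[nrow(bm), 2L]
  data.frame(
    chrom = region$chrom, chromStart = chrom_start, chromEnd = chrom_end,
    name = name, score = round(min(1000, Biostrings::score(pa))),
    strand = strand, thickStart = chrom_start, thickEnd = chrom_end,
    itemRgb = "0,0,0", blockCount = nrow(bm),
    blockSizes = paste0(paste(bm[, 2L] - bm[, 1L] + 1L, collapse = ","), ","),
    blockStarts = paste0(paste(region$start + bm[, 1L] - 1L - chrom_start,
                               collapse = ","), ","),
    stringsAsFactors = FALSE)
}

#' Write BED12 records
#' @param bed data.frame of BED12 rows (e.g. from [align_and_bed()]).
#' @param path output file.
#' @export
write_bed12 <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# BED12 row for a gene model (used in the figure and exported tracks)
gene_bed12 <- function(gene, name = gene$gene_id) {
  e <- gene$exons[[1L]]
  b <- gtf1_to_bed0(gene$start, gene$end)
  data.frame(
    chrom = gene$chrom, chromStart = b$start, chromEnd = b$end,
    name = name, score = 0L, strand = gene$strand,
    thickStart = b$start, thickEnd = b$end, itemRgb = "0,0,255",
    blockCount = nrow(e),
    blockSizes = paste0(paste(e[, 2] - e[, 1] + 1L, collapse = ","), ","),
    blockStarts = paste0(paste(e[, 1] - 1L - b$start, collapse = ","), ","),
    stringsAsFactors = FALSE)
}

#' Render splice patterns as an exon-block figure
#'
#' One track per BED row plus the two gene models; deterministic layout.
#' The device is chosen from the file extension (.pdf, .svg or .png).
#'
#' @param bed data.frame of BED12 rows.
#' @param up_gene,down_gene one-row `gene_table` slices.
#' @param path output image file.
#' @return `path`, invisibly.
#' @export
render_splice_patterns <- function(bed, up_gene, down_gene, path) {
  stopifnot(nrow(bed) >= 1L)
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         pdf = grDevices::pdf(path, width = 8, height = 4),
         svg = grDevices::svg(path, width = 8, height = 4),
         png = grDevices::png(path, width = 960, height = 480),
         grDevices::pdf(path, width = 8, height = 4))
  on.exit(grDevices::dev.off())
  tracks <- rbind(gene_bed12(up_gene), gene_bed12(down_gene), bed)
  xlim <- c(min(tracks$chromStart), max(tracks$chromEnd))
  n <- nrow(tracks)
  graphics::plot(NA, xlim = xlim, ylim = c(0, n + 1), xlab = tracks$chrom[1L],
                 ylab = "", yaxt = "n", bty = "n",
                 main = "splice patterns")
  for (i in seq_len(n)) {
    y <- n + 1 - i
    bs <- as.integer(strsplit(tracks$blockSizes[i], ",")[[1L]])
    bo <- as.integer(strsplit(tracks$blockStarts[i], ",")[[1L]])
    graphics::segments(tracks$chromStart[i], y, tracks$chromEnd[i], y,
                       col = "grey60")
    graphics::rect(tracks$chromStart[i] + bo, y - 0.3,
                   tracks$chromStart[i] + bo + bs, y + 0.3,
                   col = if (i <= 2L) "steelblue" else "firebrick",
                   border = NA)
    graphics::text(xlim[1L], y + 0.42, tracks$name[i], adj = 0, cex = 0.7)
  }
  invisible(path)
}

#' Export BED tracks and a figure for every call
#'
#' For each called pair the upstream-TSS to downstream-TTS window is
#' extracted, the consensus (or each supporting read) is aligned back to the
#' region, and a per-pair BED12 file plus figure are written.
#'
#' @param calls data.frame from [call_readthroughs()].
#' @param reads named `DNAStringSet` or path with the supporting reads.
#' @param index the `rt_index` used for calling.
#' @param genome `DNAStringSet` or FASTA path.
#' @param out_dir output directory (created if needed).
#' @param image_ext figure format, `"pdf"`, `"svg"` or `"png"`.
#' @param max_reads_per_pair cap on exported reads per pair.
#' @return character vector of written BED paths.
#' @export
export_splice_patterns <- function(calls, reads, index, genome, out_dir,
                                   image_ext = "pdf",
                                   max_reads_per_pair = 10L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_reads(reads)
  genome <- load_genome(genome)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- attr(calls, "evidence")
  written <- character(0)
  for (i in seq_len(nrow(calls))) {
    up <- index$genes[match(calls$upstream_gene_id[i],
                            index$genes$gene_id), , drop = FALSE]
    down <- index$genes[match(calls$downstream_gene_id[i],
                              index$genes$gene_id), , drop = FALSE]
    region <- extract_region(up, down, genome)
    rid <- strsplit(calls$read_ids[i], ",", fixed = TRUE)[[1L]]
    rid <- utils::head(rid[rid %in% names(reads)], max_reads_per_pair)
    bed <- NULL
    for (r in rid) {
      s <- as.character(reads[[r]])
      if (!is.null(ev)) {
        m <- match(r, ev$read_id)
        if (!is.na(m) && ev$read_strand[m] == "-") s <- rt_revcomp(s)
      }
      row <- align_and_bed(s, region, name = r, strand = calls$strand[i])
      bed <- rbind(bed, row)
    }
    if (is.null(bed)) next
    stem <- file.path(out_dir, paste0(calls$upstream_gene_id[i], "_",
                                      calls$downstream_gene_id[i]))
    write_bed12(bed, paste0(stem, ".bed"))
    render_splice_patterns(bed, up, down, paste0(stem, ".", image_ext))
    written <- c(written, paste0(stem, ".bed"))
  }
  written
}
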