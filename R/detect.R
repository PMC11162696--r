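#' Screen a read against the IAR indexes
#'
#' Counts how many of the read's minimizers (in its better-scoring
#' orientation) are present in each region's index and returns the regions
#' reaching `screen_min_hits`. This is the cheap first stage that discards
#' the vast majority of single-gene reads before confirmation.
#'
#' @param read read sequence (character).
#' @param index an `rt_index` from [build_index()].
#' @param screen_min_hits minimum total minimizer hits for a candidate
#'   region.
#' @return list of candidates; each has `iar`, `strand` (read orientation),
#'   `total_hits`, `per_gene_hits` and the raw `hits` table.
#' @export
screen_read <- function(read, index, screen_min_hits = 3) {
  rt_screen(index$ptr, as.character(read), as.integer(screen_min_hits))
}

#' Confirm read-through evidence on a single read
#'
#' Runs the full screen + confirm pipeline on one read and reports the best
#' adjacent-gene pair it supports, if any. See [call_readthroughs()] for the
#' confirmation rules.
#'
#' @inheritParams call_readthroughs
#' @param read read sequence.
#' @return one-row data.frame (same layout as the per-read evidence of
#'   [call_readthroughs()]) or `NULL` when the read is not confirmed.
#' @export
confirm_readthrough <- function(read, index, screen_min_hits = 3,
                                per_gene_min_hits = 2, order_frac = 0.75,
                                mono_frac = 0.75, rep_max = 16,
                                same_strand = TRUE) {
  ev <- rt_detect(index$ptr, as.character(read), "read", screen_min_hits,
                  per_gene_min_hits, order_frac, mono_frac, rep_max,
                  same_strand)
  if (nrow(ev) == 0L) return(NULL)
  decorate_evidence(ev, index)
}

decorate_evidence <- function(ev, index) {
  ev$up_gene_id <- index$genes$gene_id[ev$up_gene]
  ev$down_gene_id <- index$genes$gene_id[ev$down_gene]
  ev
}

#' Call read-through transcripts from a read set
#'
#' Two-stage detection: reads are screened against each IAR index, then a
#' candidate is confirmed when two transcriptionally adjacent, same-strand
#' genes each contribute at least `per_gene_min_hits` minimizer hits, the
#' upstream hits precede the downstream hits on the read (at least
#' `order_frac` of cross-gene hit pairs concordant), and read and gene
#' offsets are co-monotone within each gene (at least `mono_frac`).
#' Confirmed reads are aggregated per gene pair and pairs with fewer than
#' `min_support` supporting reads are dropped.
#'
#' @param reads a named `DNAStringSet` or a FASTA/FASTQ path.
#' @param index an `rt_index` from [build_index()].
#' @param min_support minimum supporting reads per reported pair.
#' @param screen_min_hits screening threshold (total hits per region).
#' @param per_gene_min_hits minimum hits per gene at confirmation.
#' @param order_frac required fraction of order-concordant cross-gene hit
#'   pairs.
#' @param mono_frac required fraction of co-monotone within-gene hit pairs.
#' @param rep_max minimizers occurring in more than this many postings
#'   within a region are ignored at confirmation (repeat shielding).
#' @param same_strand require the gene pair to share a strand (read-through
#'   is co-transcriptional continuation); set `FALSE` to relax.
#' @return data.frame of calls sorted by support then position, with the
#'   per-read evidence table in `attr(, "evidence")`.
#' @export
call_readthroughs <- function(reads, index, min_support = 1,
                              screen_min_hits = 3, per_gene_min_hits = 2,
                              order_frac = 0.75, mono_frac = 0.75,
                              rep_max = 16, same_strand = TRUE) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_reads(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  ev <- rt_detect(index$ptr, as.character(reads), ids,
                  as.integer(screen_min_hits), as.integer(per_gene_min_hits),
                  order_frac, mono_frac, as.integer(rep_max), same_strand)
  ev <- decorate_evidence(ev, index)

  empty <- data.frame(
    upstream_gene_id = character(0), upstream_gene_name = character(0),
    downstream_gene_id = character(0), downstream_gene_name = character(0),
    chrom = character(0), strand = character(0),
    n_supporting_reads = integer(0), upstream_hits = integer(0),
    downstream_hits = integer(0), breakpoint_read_offset = numeric(0),
    read_ids = character(0), stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) {
    attr(empty, "evidence") <- ev
    return(empty)
  }

  key <- paste(ev$up_gene, ev$down_gene, sep = "|")
  # aggregation is order-independent: reads are grouped by pair and sorted
  groups <- split(seq_len(nrow(ev)), key)
  calls <- do.call(rbind, lapply(groups, function(sel) {
    up <- ev$up_gene[sel[1L]]
    down <- ev$down_gene[sel[1L]]
    gu <- index$genes[up, , drop = FALSE]
    gd <- index$genes[down, , drop = FALSE]
    rid <- sort(ev$read_id[sel])
    data.frame(
      upstream_gene_id = gu$gene_id, upstream_gene_name = gu$gene_name,
      downstream_gene_id = gd$gene_id, downstream_gene_name = gd$gene_name,
      chrom = gu$chrom, strand = ev$gene_strand[sel[1L]],
      n_supporting_reads = length(sel),
      upstream_hits = sum(ev$up_hits[sel]),
      downstream_hits = sum(ev$down_hits[sel]),
      breakpoint_read_offset = stats::median(ev$transition[sel]),
      read_ids = paste(rid, collapse = ","),
      stringsAsFactors = FALSE)
  }))
  calls <- calls[calls$n_supporting_reads >= min_support, , drop = FALSE]
  if (nrow(calls) == 0L) {
    attr(empty, "evidence") <- ev
    return(empty)
  }
  pos <- index$genes$start[match(calls$upstream_gene_id, index$genes$gene_id)]
  o <- order(-calls$n_supporting_reads, calls$chrom, pos)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "evidence") <- ev
  calls
}

#' Recall, precision and F1 against a truth set
#'
#' A call is a true positive when its (upstream, downstream) gene pair,
#' in transcription order, appears in the truth table.
#'
#' @param calls data.frame from [call_readthroughs()] (or any frame with
#'   `upstream_gene_id` / `downstream_gene_id` columns).
#' @param truth data.frame with `up_gene_id` and `down_gene_id` columns.
#' @return list with `recall`, `precision`, `f1`, `tp`, `fp`, `fn`. With an
#'   empty truth set recall and f1 are `NA`.
#' @examples
#' calls <- data.frame(upstream_gene_id = "A", downstream_gene_id = "B")
#' truth <- data.frame(up_gene_id = c("A", "C"),
#'                     down_gene_id = c("B", "D"))
#' compute_metrics(calls, truth)$recall  # 0.5
#' @export
compute_metrics <- function(calls, truth) {
  call_keys <- unique(paste(calls$upstream_gene_id, calls$downstream_gene_id,
                            sep = "|"))
  truth_keys <- unique(paste(truth$up_gene_id, truth$down_gene_id,
                             sep = "|"))
  if (length(truth_keys) == 0L || nrow(truth) == 0L) {
    tp <- 0L
    fp <- length(call_keys)
    return(list(recall = NA_real_,
                precision = if (fp + tp > 0) 0 else NA_real_,
                f1 = NA_real_, tp = tp, fp = fp, fn = 0L))
  }
  tp <- sum(call_keys %in% truth_keys)
  fp <- sum(!call_keys %in% truth_keys)
  fn <- sum(!truth_keys %in% call_keys)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && (recall + precision) > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  list(recall = recall, precision = precision, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Write calls to the tab-separated output format
#' @param calls data.frame from [call_readthroughs()].
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
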