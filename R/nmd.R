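#' Anchor supporting reads to the upstream and downstream gene models
#'
#' Each read is oriented to the gene strand (automatically, unless
#' `read_strands` is given) and its prefix is matched against the upstream
#' spliced transcript by edit-distance dynamic programming, allowing the
#' transcript 5' end to be truncated; the suffix is matched against the
#' downstream transcript the same way. The read segment between the end of
#' the upstream transcript and the start of the downstream transcript is the
#' intergenic insert candidate. Reads whose anchoring edit distance exceeds
#' the band `max(band_min, band_scale * aligned length)` are excluded.
#'
#' @param reads named character vector or `DNAStringSet` of supporting
#'   reads, in sequencing orientation.
#' @param up_gene,down_gene one-row `gene_table` slices (transcription
#'   order).
#' @param genome `DNAStringSet` or FASTA path.
#' @param read_strands optional `"+"`/`"-"` per read (from detection
#'   evidence); `"-"` reads are reverse-complemented before anchoring.
#' @param band_min,band_scale anchoring band: a read is kept when its edit
#'   distance is at most `max(band_min, band_scale * aligned_length)`.
#' @return data.frame with per-read anchor coordinates, edit distances,
#'   the extracted `insert` and an `anchored` flag.
#' @export
anchor_reads <- function(reads, up_gene, down_gene, genome,
                         read_strands = NULL, band_min = 20,
                         band_scale = 0.2) {
  genome <- load_genome(genome)
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%03d", seq_along(seqs))
  up_mrna <- gene_spliced_seq(up_gene, genome)
  down_mrna <- gene_spliced_seq(down_gene, genome)

  anchor_one <- function(s) {
    a <- rt_anchor_prefix(up_mrna, s)
    b <- rt_anchor_suffix(down_mrna, s)
    list(up_end = a$end, up_dist = a$dist,
         down_start = b$start, down_dist = b$dist,
         total = a$dist + b$dist)
  }

  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    if (!is.null(read_strands)) {
      strand <- read_strands[i]
      if (strand == "-") s <- rt_revcomp(s)
      r <- anchor_one(s)
    } else {
      fw <- anchor_one(s)
      rv <- anchor_one(rt_revcomp(s))
      if (fw$total <= rv$total) {
        r <- fw; strand <- "+"
      } else {
        r <- rv; strand <- "-"; s <- rt_revcomp(s)
      }
    }
    band_up <- max(band_min, band_scale * r$up_end)
    band_down <- max(band_min, band_scale * (nchar(s) - r$down_start + 1))
    ok <- r$up_dist <= band_up && r$down_dist <= band_down &&
      r$down_start > 1 && r$up_end < nchar(s)
    insert <- if (ok && r$down_start > r$up_end + 1)
      substr(s, r$up_end + 1, r$down_start - 1) else ""
    data.frame(read_id = ids[i], strand = strand, up_end = r$up_end,
               down_start = r$down_start, up_dist = r$up_dist,
               down_dist = r$down_dist, anchored = ok, insert = insert,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus of intergenic insert segments
#'
#' Star-alignment consensus: the medoid segment (minimum total edit distance
#' to the others) is the backbone; every other segment is globally aligned
#' to it and a per-column majority vote is taken over bases and gaps, with
#' ties resolved toward the backbone base. Insertions relative to the
#' backbone are adopted when a majority of segments insert at the same
#' backbone gap. A single segment is returned unchanged.
#'
#' @param segments character vector of insert sequences (may include empty
#'   strings from reads with a clean splice junction).
#' @return consensus DNA string.
#' @export
consensus_insert <- function(segments) {
  segments <- as.character(segments)
  if (length(segments) == 0L) stop("consensus_insert: no segments")
  if (length(segments) == 1L) return(segments)
  n <- length(segments)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- rt_edit_distance(segments[i], segments[j], -1L)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  bb <- segments[which.min(rowSums(D))]
  if (!nzchar(bb)) return("")
  others <- segments[-which.min(rowSums(D))]
  others <- others[nzchar(others)]
  if (length(others) == 0L) return(bb)

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  L <- nchar(bb)
  bases <- c("A", "C", "G", "T", "-")
  votes <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(bases, NULL))
  bbv <- strsplit(bb, "")[[1L]]
  for (p in seq_len(L)) votes[bbv[p], p] <- votes[bbv[p], p] + 1L
  ins_at <- vector("list", L + 1L)  # insertions after backbone position p

  for (s in others) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(s),
      subject = Biostrings::DNAString(bb), type = "global",
      substitutionMatrix = submat, gapOpening = 1, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    bpos <- 0L
    pending <- ""
    for (t in seq_along(as_)) {
      if (as_[t] == "-") {
        pending <- paste0(pending, ap[t])
      } else {
        if (nzchar(pending)) {
          ins_at[[bpos + 1L]] <- c(ins_at[[bpos + 1L]], pending)
          pending <- ""
        }
        bpos <- bpos + 1L
        b <- ap[t]
        if (!b %in% bases) b <- "-"
        votes[b, bpos] <- votes[b, bpos] + 1L
      }
    }
    if (nzchar(pending)) ins_at[[L + 1L]] <- c(ins_at[[L + 1L]], pending)
  }

  total <- length(others) + 1L
  out <- character(0)
  for (p in 0:L) {
    insv <- ins_at[[p + 1L]]
    if (length(insv) > total / 2) {
      tab <- sort(table(insv), decreasing = TRUE)
      out <- c(out, names(tab)[1L])
    }
    if (p < L) {
      col <- votes[, p + 1L]
      best <- bases[col == max(col)]
      b <- if (bbv[p + 1L] %in% best) bbv[p + 1L] else best[1L]
      if (b != "-") out <- c(out, b)
    }
  }
  paste(out, collapse = "")
}

#' Classify a read-through transcript as NMD-prone or protein-coding
#'
#' Builds the fused transcript model (upstream spliced exons, consensus
#' intergenic insert, downstream spliced exons), translates in the upstream
#' CDS frame from the upstream start codon, takes the first in-frame stop at
#' or after the boundary (last upstream) exon as the candidate premature
#' termination codon, and applies the 55-nt exon-junction rule: the
#' transcript is NMD-prone when that stop lies more than 55 nt upstream of
#' the last exon-exon junction of the fused model, and escapes otherwise
#' (55 exactly counts as within). An empty insert implies a clean splice
#' junction between the boundary exon and the downstream gene; a retained
#' insert is treated as contiguous with its flanking exons.
#'
#' @param up_gene,down_gene one-row `gene_table` slices in transcription
#'   order; the upstream gene must have a CDS, otherwise the classification
#'   is `"indeterminate"`.
#' @param insert consensus intergenic insert (possibly `""`).
#' @param genome `DNAStringSet` or FASTA path.
#' @return list of class `fate_result` with `consensus_insert`,
#'   `ptc_found`, `stop_codon`, `distance_to_last_junction` and
#'   `classification` (`"NMD"`, `"protein_coding"` or `"indeterminate"`),
#'   plus a `note` explaining edge cases.
#' @export
classify_fate <- function(up_gene, down_gene, insert, genome) {
  genome <- load_genome(genome)
  res <- list(consensus_insert = insert, ptc_found = FALSE,
              stop_codon = NA_character_,
              distance_to_last_junction = NA_real_,
              classification = "indeterminate", note = "")
  class(res) <- "fate_result"
  if (is.na(up_gene$cds_start)) {
    res$note <- "upstream gene has no annotated CDS"
    return(res)
  }
  up_mrna <- gene_spliced_seq(up_gene, genome)
  down_mrna <- gene_spliced_seq(down_gene, genome)
  fused <- toupper(paste0(up_mrna, insert, down_mrna))

  exon_widths <- function(g) {
    e <- g$exons[[1L]]
    w <- e[, 2] - e[, 1] + 1L
    if (g$strand == "-") rev(w) else w  # sense (transcription) order
  }
  up_w <- exon_widths(up_gene)
  down_w <- exon_widths(down_gene)
  L_up <- sum(up_w)
  L_ins <- nchar(insert)
  n_up <- length(up_w)
  n_down <- length(down_w)

  junctions <- c(
    if (n_up > 1L) cumsum(up_w)[-n_up],
    if (L_ins == 0L) L_up,                     # clean splice at the boundary
    if (n_down > 1L) L_up + L_ins + cumsum(down_w)[-n_down])
  if (length(junctions) == 0L) {
    res$classification <- "protein_coding"
    res$note <- "fused model has no exon-exon junction; NMD not possible"
    return(res)
  }
  last_junction <- max(junctions)

  cds_sense_start <- if (up_gene$strand == "+") up_gene$cds_start else
    up_gene$cds_end
  atg <- spliced_pos(up_gene, cds_sense_start)
  if (is.na(atg)) {
    res$note <- "upstream CDS start not exonic"
    return(res)
  }
  boundary_start <- if (n_up > 1L) cumsum(up_w)[n_up - 1L] + 1L else 1L

  starts <- seq.int(atg, nchar(fused) - 2L, by = 3L)
  codons <- substring(fused, starts, starts + 2L)
  hit <- which(codons %in% c("TAA", "TAG", "TGA") & starts >= boundary_start)
  if (length(hit) == 0L) {
    res$classification <- "protein_coding"
    res$note <- "no in-frame stop at or after the boundary exon"
    return(res)
  }
  i <- hit[1L]
  ptc_end <- starts[i] + 2L
  res$ptc_found <- TRUE
  res$stop_codon <- codons[i]
  res$distance_to_last_junction <- last_junction - ptc_end
  res$classification <- if (res$distance_to_last_junction > 55)
    "NMD" else "protein_coding"
  res
}

#' @export
print.fate_result <- function(x, ...) {
  cat(sprintf("fate: %s (stop %s, distance to last junction %s nt)%s\n",
              x$classification,
              ifelse(is.na(x$stop_codon), "none", x$stop_codon),
              ifelse(is.na(x$distance_to_last_junction), "NA",
                     format(x$distance_to_last_junction)),
              ifelse(nzchar(x$note), paste0(" [", x$note, "]"), "")))
  invisible(x)
}

#' Predict the fate of every called read-through transcript
#'
#' Driver over [anchor_reads()], [consensus_insert()] and [classify_fate()]:
#' for each call, the supporting reads are anchored, their intergenic
#' segments reciprocally corrected into a consensus, and the fused model
#' classified by the 55-nt rule.
#'
#' @param calls data.frame from [call_readthroughs()] (its per-read
#'   evidence attribute supplies read orientations when present).
#' @param reads named `DNAStringSet` or FASTA/FASTQ path with at least the
#'   supporting reads.
#' @param index the `rt_index` used for calling (provides gene models).
#' @param genome `DNAStringSet` or FASTA path.
#' @param ... band parameters forwarded to [anchor_reads()].
#' @return `calls` with added columns `stop_codon`, `distance_nt`,
#'   `classification`, `n_anchored` and `insert_len`.
#' @export
predict_fate <- function(calls, reads, index, genome, ...) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_reads(reads)
  genome <- load_genome(genome)
  ev <- attr(calls, "evidence")
  out <- calls
  out$stop_codon <- NA_character_
  out$distance_nt <- NA_real_
  out$classification <- NA_character_
  out$n_anchored <- 0L
  out$insert_len <- NA_integer_
  for (i in seq_len(nrow(calls))) {
    rid <- strsplit(calls$read_ids[i], ",", fixed = TRUE)[[1L]]
    rid <- rid[rid %in% names(reads)]
    up <- index$genes[match(calls$upstream_gene_id[i],
                            index$genes$gene_id), , drop = FALSE]
    down <- index$genes[match(calls$downstream_gene_id[i],
                              index$genes$gene_id), , drop = FALSE]
    strands <- NULL
    if (!is.null(ev)) {
      m <- match(rid, ev$read_id)
      if (!anyNA(m)) strands <- ev$read_strand[m]
    }
    if (length(rid) == 0L) {
      out$classification[i] <- "indeterminate"
      next
    }
    anc <- anchor_reads(setNames(as.character(reads[rid]), rid), up, down,
                        genome, read_strands = strands, ...)
    kept <- anc[anc$anchored, , drop = FALSE]
    out$n_anchored[i] <- nrow(kept)
    if (nrow(kept) == 0L) {
      out$classification[i] <- "indeterminate"
      next
    }
    cons <- consensus_insert(kept$insert)
    fate <- classify_fate(up, down, cons, genome)
    out$stop_codon[i] <- fate$stop_codon
    out$distance_nt[i] <- fate$distance_to_last_junction
    out$classification[i] <- fate$classification
    out$insert_len[i] <- nchar(cons)
  }
  out
}
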