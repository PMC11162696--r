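#' Construct a gene table
#'
#' A `gene_table` is the package's annotation container: one row per gene
#' with 1-based inclusive genomic coordinates, an ordered exon model (union
#' over transcripts) and an optional CDS span.
#'
#' @param gene_id,gene_name character vectors.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene span.
#' @param exons list of two-column integer matrices (`start`, `end`), one per
#'   gene, sorted and non-overlapping, each exon within the gene span.
#' @param cds_start,cds_end optional 1-based inclusive CDS span (NA if the
#'   gene is non-coding).
#' @return A `data.frame` of class `gene_table`.
#' @export
gene_table <- function(gene_id, gene_name = gene_id, chrom, strand, start,
                       end, exons, cds_start = NA_integer_,
                       cds_end = NA_integer_) {
  n <- length(gene_id)
  df <- data.frame(gene_id = as.character(gene_id),
                   gene_name = as.character(gene_name),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   cds_start = as.integer(rep_len(cds_start, n)),
                   cds_end = as.integer(rep_len(cds_end, n)),
                   stringsAsFactors = FALSE)
  df$exons <- lapply(exons, function(e) {
    e <- matrix(as.integer(e), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    e[order(e[, 1]), , drop = FALSE]
  })
  validate_gene_table(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_gene_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start > df$end)) stop("gene start must be <= end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(df))) {
    e <- df$exons[[i]]
    if (nrow(e) == 0L) stop("gene ", df$gene_id[i], " has no exons")
    if (any(e[, 1] > e[, 2])) stop("exon start > end in ", df$gene_id[i])
    if (any(e[, 1] < df$start[i]) || any(e[, 2] > df$end[i]))
      stop("exon outside gene span in ", df$gene_id[i])
    if (nrow(e) > 1L && any(e[-1L, 1] <= e[-nrow(e), 2]))
      stop("overlapping exons in ", df$gene_id[i])
  }
  invisible(df)
}

#' Gene lengths (bp, end - start + 1)
#' @param genes a `gene_table`.
#' @return integer vector.
#' @export
gene_length <- function(genes) genes$end - genes$start + 1L

# union-merge of possibly overlapping intervals (two-column matrix)
merge_intervals <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  r <- IRanges::reduce(IRanges::IRanges(m[, 1], m[, 2]))
  cbind(start = IRanges::start(r), end = IRanges::end(r))
}

#' Parse a GTF annotation into a gene table
#'
#' Reads an Ensembl-dialect GTF and builds one record per `gene_id`:
#' `gene` rows define the span, `exon` rows are union-merged across
#' transcripts, and the CDS span is the min/max over CDS rows of the
#' canonical (longest-CDS) transcript. A gene with no exon rows is retained
#' with a single exon equal to its span (with a warning).
#'
#' @param gtf_path path to a GTF file.
#' @param feature_policy exon merging policy; only `"union"` is implemented.
#' @return A `gene_table`, sorted by (chrom, start).
#' @export
parse_annotation <- function(gtf_path, feature_policy = "union") {
  feature_policy <- match.arg(feature_policy, "union")
  lines <- readLines(gtf_path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body) == 0L) {
    return(gene_table(character(0), character(0), character(0), character(0),
                      integer(0), integer(0), list()))
  }
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L))
    stop("malformed GTF line ", body[which(nf < 9L)[1L]], " in ", gtf_path,
         ": expected 9 tab-separated fields, got ", nf[which(nf < 9L)[1L]])

  gr <- rtracklayer::import(gtf_path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  feat <- as.character(meta$type)
  gid <- as.character(meta$gene_id)
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  chr <- as.character(GenomicRanges::seqnames(gr))
  strd <- as.character(GenomicRanges::strand(gr))
  gname <- if ("gene_name" %in% colnames(meta))
    as.character(meta$gene_name) else gid
  txid <- if ("transcript_id" %in% colnames(meta))
    as.character(meta$transcript_id) else rep(NA_character_, length(gr))

  ids <- unique(gid[!is.na(gid)])
  out <- lapply(ids, function(g) {
    sel <- which(gid == g)
    grow <- sel[feat[sel] == "gene"]
    erow <- sel[feat[sel] == "exon"]
    crow <- sel[feat[sel] == "CDS"]
    if (length(erow)) {
      ex <- merge_intervals(cbind(st[erow], en[erow]))
    } else {
      ex <- NULL
    }
    if (length(grow)) {
      gs <- st[grow[1L]]; ge <- en[grow[1L]]
      chrom <- chr[grow[1L]]; strand <- strd[grow[1L]]
      name <- gname[grow[1L]]
    } else {
      gs <- min(st[sel]); ge <- max(en[sel])
      chrom <- chr[sel[1L]]; strand <- strd[sel[1L]]
      name <- gname[sel[1L]]
    }
    if (is.null(ex)) {
      warning("gene ", g, " has no exon rows; using its span as one exon")
      ex <- cbind(start = gs, end = ge)
    }
    gs <- min(gs, ex[, 1]); ge <- max(ge, ex[, 2])
    cs <- NA_integer_; ce <- NA_integer_
    if (length(crow)) {
      ctx <- txid[crow]
      if (all(is.na(ctx))) {
        keep <- crow
      } else {
        w <- tapply(en[crow] - st[crow] + 1L, ctx, sum)
        keep <- crow[ctx == names(w)[which.max(w)]]
      }
      cs <- min(st[keep]); ce <- max(en[keep])
    }
    list(gene_id = g, gene_name = ifelse(is.na(name), g, name),
         chrom = chrom, strand = if (strand %in% c("+", "-")) strand else "+",
         start = gs, end = ge, exons = ex, cds_start = cs, cds_end = ce)
  })

  gt <- gene_table(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    gene_name = vapply(out, `[[`, "", "gene_name"),
    chrom = vapply(out, `[[`, "", "chrom"),
    strand = vapply(out, `[[`, "", "strand"),
    start = vapply(out, function(x) as.integer(x$start), 1L),
    end = vapply(out, function(x) as.integer(x$end), 1L),
    exons = lapply(out, `[[`, "exons"),
    cds_start = vapply(out, function(x) as.integer(x$cds_start), 1L),
    cds_end = vapply(out, function(x) as.integer(x$cds_end), 1L))
  sort_gene_table(gt)
}

sort_gene_table <- function(gt) {
  o <- order(gt$chrom, gt$start, gt$end)
  gt <- gt[o, , drop = FALSE]
  rownames(gt) <- NULL
  class(gt) <- c("gene_table", "data.frame")
  gt
}

# position in the spliced sense transcript (1-based) of a genomic coordinate;
# NA if the position is intronic
spliced_pos <- function(gene, genomic_pos) {
  e <- gene$exons[[1L]]
  lens <- e[, 2] - e[, 1] + 1L
  if (gene$strand == "+") {
    cum <- cumsum(c(0L, lens[-length(lens)]))
    for (i in seq_len(nrow(e))) {
      if (genomic_pos >= e[i, 1] && genomic_pos <= e[i, 2])
        return(cum[i] + genomic_pos - e[i, 1] + 1L)
    }
  } else {
    # sense order walks exons right to left
    ord <- rev(seq_len(nrow(e)))
    cum <- cumsum(c(0L, lens[rev(seq_along(lens))][-length(lens)]))
    for (j in seq_along(ord)) {
      i <- ord[j]
      if (genomic_pos >= e[i, 1] && genomic_pos <= e[i, 2])
        return(cum[j] + e[i, 2] - genomic_pos + 1L)
    }
  }
  NA_integer_
}

# spliced sense mRNA sequence of one gene row
gene_spliced_seq <- function(gene, genome) {
  chrom_seq <- genome_chrom(genome, gene$chrom)
  e <- gene$exons[[1L]]
  parts <- vapply(seq_len(nrow(e)), function(i)
    as.character(Biostrings::subseq(chrom_seq, e[i, 1], e[i, 2])), "")
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") rt_revcomp(s) else s
}

# whole-span sense (annotated-strand) genomic sequence of one gene row
gene_sense_seq <- function(gene, genome) {
  chrom_seq <- genome_chrom(genome, gene$chrom)
  s <- as.character(Biostrings::subseq(chrom_seq, gene$start, gene$end))
  if (gene$strand == "-") rt_revcomp(s) else s
}
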