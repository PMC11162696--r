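# I/O helpers: FASTA/FASTQ via Biostrings, GTF writing, genome access.

# accept a DNAStringSet or a FASTA path
load_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(Biostrings::readDNAStringSet(x))
  stop("genome must be a DNAStringSet or a FASTA path")
}

genome_chrom <- function(genome, chrom) {
  nm <- sub("\\s.*$", "", names(genome))
  i <- match(chrom, nm)
  if (is.na(i)) stop("chromosome '", chrom, "' not found in the genome")
  genome[[i]]
}

#' Read long reads from FASTA or FASTQ
#'
#' The format is chosen from the file extension (`.fq`/`.fastq`, optionally
#' gzipped, are FASTQ; anything else FASTA). Read names are truncated at the
#' first whitespace.
#'
#' @param path input file.
#' @return a named `DNAStringSet`.
#' @export
read_reads <- function(path) {
  fq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  x <- Biostrings::readDNAStringSet(path, format = if (fq) "fastq" else "fasta")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

write_fastq <- function(seqs, path, qual_char = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- names(seqs)
  ss <- as.character(seqs)
  for (i in seq_along(ss)) {
    writeLines(c(paste0("@", nm[i]), ss[i], "+",
                 strrep(qual_char, nchar(ss[i]))), con)
  }
  invisible(path)
}

# write a gene_table as Ensembl-dialect GTF (gene / exon / CDS rows,
# one transcript per gene named <gene_id>.t1)
write_gtf <- function(genes, path, source = "readthroughr") {
  lines <- character(0)
  attr_str <- function(gid, gname, tx = NULL) {
    s <- sprintf('gene_id "%s"; gene_name "%s";', gid, gname)
    if (!is.null(tx)) s <- paste0(s, sprintf(' transcript_id "%s";', tx))
    s
  }
  row9 <- function(chrom, feat, start, end, strand, attrs) {
    paste(chrom, source, feat, start, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    tx <- paste0(g$gene_id, ".t1")
    lines <- c(lines, row9(g$chrom, "gene", g$start, g$end, g$strand,
                           attr_str(g$gene_id, g$gene_name)))
    e <- g$exons[[1L]]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, row9(g$chrom, "exon", e[j, 1], e[j, 2], g$strand,
                             attr_str(g$gene_id, g$gene_name, tx)))
    }
    if (!is.na(g$cds_start)) {
      for (j in seq_len(nrow(e))) {
        a <- max(e[j, 1], g$cds_start)
        b <- min(e[j, 2], g$cds_end)
        if (a <= b)
          lines <- c(lines, row9(g$chrom, "CDS", a, b, g$strand,
                                 attr_str(g$gene_id, g$gene_name, tx)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# plain key=value config files for the CLI ("defaults < file < flags")
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  vals <- trimws(vapply(kv, `[`, "", 2L))
  names(vals) <- trimws(vapply(kv, `[`, "", 1L))
  as.list(vals)
}
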