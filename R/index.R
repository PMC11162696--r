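#' Index modulus rule
#'
#' Home slots in an IAR's slot array are assigned modulo the number of
#' minimizers `MI_j` when that count reaches the floor `mo`, and modulo `mo`
#' otherwise, so tiny regions never get a degenerate modulus.
#'
#' @param n_minimizers minimizer count of the region (`MI_j`).
#' @param mo modulus floor.
#' @return the modulus used for home-slot assignment.
#' @examples
#' iar_modulus(5, 3)  # 5
#' iar_modulus(2, 8)  # 8
#' @export
iar_modulus <- function(n_minimizers, mo) {
  ifelse(n_minimizers >= mo, n_minimizers, mo)
}

#' Build a slot-array index for one IAR
#'
#' Stores minimizer postings in a contiguous array addressed by
#' `hash %% modulus` (see [iar_modulus()]); collisions are resolved by
#' linear probing with a 1.3x capacity slack, so every inserted posting
#' remains retrievable.
#'
#' @param minimizers data.frame with columns `hash` (64-bit hex),
#'   `gene_ordinal` (1-based gene index within the IAR) and `offset`
#'   (0-based position within the gene's sense sequence).
#' @param mo modulus floor.
#' @return an `iar_index` handle.
#' @export
build_iar_index <- function(minimizers, mo = 4096) {
  stopifnot(mo >= 1)
  ptr <- rt_build_single(as.character(minimizers$hash),
                         as.integer(minimizers$gene_ordinal) - 1L,
                         as.integer(minimizers$offset), mo)
  structure(list(ptr = ptr, mo = mo), class = "iar_index")
}

#' Query an IAR index by hash
#' @param index an `iar_index` from [build_iar_index()].
#' @param hash 64-bit hex hash.
#' @return data.frame of postings (`hash`, `gene_ordinal`, `offset`) in
#'   insertion order; zero rows when the hash is absent.
#' @export
query_index <- function(index, hash) {
  df <- rt_single_query(index$ptr, hash)
  data.frame(hash = df$hash, gene_ordinal = df$gene + 1L,
             offset = df$offset, stringsAsFactors = FALSE)
}

#' @export
print.iar_index <- function(x, ...) {
  s <- rt_single_stats(x$ptr)
  cat(sprintf("iar_index: %g minimizers, modulus %g, capacity %g\n",
              s$n_minimizers, s$modulus, s$capacity))
  invisible(x)
}

#' Slot statistics of an IAR index
#' @param index an `iar_index`.
#' @return list with `n_minimizers`, `modulus`, `capacity`.
#' @export
index_stats <- function(index) rt_single_stats(index$ptr)

#' Build the full read-through index
#'
#' Partitions the annotation into IARs, sketches every gene's
#' annotated-strand genomic sequence and builds one independent slot-array
#' index per region.
#'
#' @param genome `DNAStringSet` or FASTA path covering all gene spans.
#' @param genes a `gene_table` or a GTF path.
#' @param params a [sketch_params()] object.
#' @return an `rt_index` object.
#' @export
build_index <- function(genome, genes, params = sketch_params()) {
  genome <- load_genome(genome)
  if (is.character(genes)) genes <- parse_annotation(genes)
  iars <- partition_iars(genes, params$thr)
  flat <- iar_flat_genes(iars)
  seqs <- vapply(seq_len(nrow(flat)), function(i)
    gene_sense_seq(flat[i, , drop = FALSE], genome), "")
  ptr <- rt_build_multi(seqs, as.integer(flat$iar_id), flat$strand,
                        params$k, params$s, params$st, params$mo)
  structure(list(ptr = ptr, params = params, genes = flat, iars = iars),
            class = "rt_index")
}

#' @export
print.rt_index <- function(x, ...) {
  st <- rt_multi_stats(x$ptr)
  cat(sprintf("rt_index: %d genes in %d IARs (k=%d s=%d st=%d mo=%g)\n",
              nrow(x$genes), nrow(st$iars), x$params$k, x$params$s,
              x$params$st, x$params$mo))
  invisible(x)
}

#' Serialize an index to a versioned binary blob
#'
#' The blob holds the parameters, the IAR table and the raw slot arrays;
#' round-trips are bit-exact. Gene metadata travels alongside so that
#' [index_read()] restores a fully usable object.
#'
#' @param index an `rt_index`.
#' @return a raw vector.
#' @export
index_serialize <- function(index) rt_serialize(index$ptr)

#' Write / read an index file
#' @param index an `rt_index`.
#' @param path output file (conventionally `.rtidx`).
#' @return `index_write` returns `path`; `index_read` an `rt_index`.
#' @export
index_write <- function(index, path) {
  payload <- list(format = "rtidx-1", blob = index_serialize(index),
                  params = unclass(index$params), genes = index$genes)
  con <- file(path, "wb")
  on.exit(close(con))
  serialize(payload, con, xdr = TRUE)
  invisible(path)
}

#' @rdname index_write
#' @export
index_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  payload <- unserialize(con)
  if (!identical(payload$format, "rtidx-1")) stop("not an rtidx file")
  params <- do.call(sketch_params, payload$params[
    c("k", "s", "st", "thr", "mo", "min_support")])
  genes <- payload$genes
  iars <- lapply(split(seq_len(nrow(genes)), genes$iar_id), function(sel) {
    g <- genes[sel, setdiff(colnames(genes), c("iar_id", "ordinal")),
               drop = FALSE]
    rownames(g) <- NULL
    class(g) <- c("gene_table", "data.frame")
    structure(list(iar_id = genes$iar_id[sel[1L]], chrom = g$chrom[1L],
                   genes = g,
                   span = c(start = min(g$start), end = max(g$end))),
              class = "iar")
  })
  structure(list(ptr = rt_deserialize(payload$blob), params = params,
                 genes = genes, iars = unname(iars)),
            class = "rt_index")
}
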