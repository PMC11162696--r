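#' 2-bit pack a k-mer
#'
#' Encodes A/C/G/T (case-insensitive) as 0/1/2/3, most-significant base
#' first. Returns `NA` for k-mers containing ambiguous bases. Numeric codes
#' are exact only up to k = 26 (2^52 < 2^53); the compiled core packs up to
#' k = 32 internally.
#'
#' @param seq character vector of k-mers.
#' @return numeric vector of codes, `NA` where unencodable.
#' @examples
#' encode_kmer("ACGT")  # 27
#' @export
encode_kmer <- function(seq) {
  vapply(seq, function(x) rt_encode_kmer(x), 0, USE.NAMES = FALSE)
}

#' Bijective avalanche hash of a packed word
#'
#' Applies the 64-bit invertible multiply-xorshift mix used throughout the
#' index. Hashes are returned as 16-digit lowercase hex so the full 64-bit
#' value survives the R boundary; lexicographic order on these strings
#' equals numeric order.
#'
#' @param x numeric codes (< 2^53) or 16-digit hex strings.
#' @return character vector of 64-bit hashes in hex.
#' @seealso [hash_invert()] for the inverse map, [kmer_hash()] to hash DNA
#'   directly.
#' @export
avalanche_hash <- function(x) {
  if (is.character(x)) vapply(x, rt_hash_hex, "", USE.NAMES = FALSE)
  else vapply(x, rt_hash_code, "", USE.NAMES = FALSE)
}

#' Invert the avalanche hash
#' @param hex character vector of 64-bit hex hashes.
#' @return character vector of the pre-images, as 16-digit hex words.
#' @export
hash_invert <- function(hex) {
  vapply(hex, rt_hash_invert, "", USE.NAMES = FALSE)
}

#' Hash k-mers directly
#' @param kmers character vector of DNA k-mers (all the same length, <= 32).
#' @return 64-bit hex hashes; `NA` for k-mers with ambiguous bases.
#' @export
kmer_hash <- function(kmers) as.character(rt_kmer_hash(kmers))

#' Minimizer of a single window
#'
#' Returns the k-mer with the minimum hash among the `s - k + 1` k-mers of
#' one window. The production avalanche hash is used unless `hash_fn` is
#' supplied (e.g. `encode_kmer` for an identity-hash oracle); k-mers with
#' ambiguous bases never win.
#'
#' @param window DNA string.
#' @param params a [sketch_params()] object (only `k` is used here).
#' @param hash_fn optional function mapping a k-mer string to a numeric or
#'   otherwise comparable hash value.
#' @return list with `hash` and 0-based `offset`, or an empty list when all
#'   k-mers are unencodable.
#' @export
window_minimizer <- function(window, params = sketch_params(),
                             hash_fn = NULL) {
  k <- params$k
  if (nchar(window) < k) return(list())
  if (is.null(hash_fn)) {
    res <- rt_window_minimizer(window, k)
    if (length(res$hash) == 0L) return(list())
    return(list(hash = res$hash, offset = res$offset))
  }
  n <- nchar(window) - k + 1L
  kmers <- substring(window, seq_len(n), seq_len(n) + k - 1L)
  h <- unlist(lapply(kmers, hash_fn), use.names = FALSE)
  ok <- !is.na(h)
  if (!any(ok)) return(list())
  ho <- h[ok]
  idx <- which(ok)[which(ho == min(ho))[1L]]  # leftmost minimum
  list(hash = h[idx], offset = idx - 1L)
}

#' Sketch a gene sequence with sliding-window minimizers
#'
#' Windows of length `s` start at 0, `st`, `2*st`, ...; when the last full
#' window does not end at the sequence end one extra window anchored at
#' `length - s` is added, so 3' ends are never unsketched. Sequences shorter
#' than `s` are sketched as a single truncated window. Duplicate
#' (hash, offset) pairs are collapsed.
#'
#' @param seq DNA string (the gene's annotated-strand genomic sequence).
#' @param params a [sketch_params()] object.
#' @return data.frame with `hash` (hex), 0-based `offset`, and `kmer`.
#' @export
sketch_gene <- function(seq, params = sketch_params()) {
  if (nchar(seq) < params$k) {
    message("sequence shorter than k; empty sketch")
    return(data.frame(hash = character(0), offset = integer(0),
                      kmer = character(0), stringsAsFactors = FALSE))
  }
  df <- rt_sketch(seq, params$k, params$s, params$st)
  df$kmer <- substring(seq, df$offset + 1L, df$offset + params$k)
  df
}

#' Sketch a read in both orientations
#'
#' Applies the same window scheme as [sketch_gene()] to the read and to its
#' reverse complement; each minimizer is tagged with the orientation it came
#' from. The reference index stores only annotated-strand sequence, so the
#' query side must cover both orientations.
#'
#' @param seq read sequence.
#' @param params a [sketch_params()] object.
#' @return data.frame with `hash`, 0-based `offset` (within the stated
#'   orientation) and `strand` (`"+"` forward, `"-"` reverse complement).
#' @export
sketch_read <- function(seq, params = sketch_params()) {
  if (nchar(seq) < params$k) {
    return(data.frame(hash = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  rt_sketch_read(seq, params$k, params$s, params$st)
}
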