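#' Sketching and indexing parameters
#'
#' Bundles the tunable parameters of the minimizer sketch and the IAR index.
#' The `"default"` preset (k = 25, s = 40, st = 9) targets high-quality
#' reads; the `"noisy"` preset (k = 15, s = 24, st = 9) trades specificity
#' for error tolerance on noisy data.
#'
#' @param k k-mer length in bases (1..32).
#' @param s sliding-window length in bases; must be >= `k`.
#' @param st window step in bases (1..`s`).
#' @param thr maximum intergenic gap (bp) for two consecutive genes to share
#'   an isolated active region.
#' @param mo floor on the index modulus: an IAR with fewer than `mo`
#'   minimizers is indexed modulo `mo` instead of its minimizer count.
#' @param min_support minimum number of supporting reads for a reported
#'   read-through pair.
#' @param preset `"default"` or `"noisy"`; presets set `k`, `s`, `st` and are
#'   overridden by explicitly supplied values.
#' @return An object of class `sketch_params`.
#' @examples
#' sketch_params()
#' sketch_params(preset = "noisy")
#' @export
sketch_params <- function(k = NULL, s = NULL, st = NULL, thr = 1e5,
                          mo = 4096, min_support = 1,
                          preset = c("default", "noisy")) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 default = list(k = 25L, s = 40L, st = 9L),
                 noisy   = list(k = 15L, s = 24L, st = 9L))
  p <- list(k = as.integer(if (is.null(k)) base$k else k),
            s = as.integer(if (is.null(s)) base$s else s),
            st = as.integer(if (is.null(st)) base$st else st),
            thr = as.numeric(thr),
            mo = as.numeric(mo),
            min_support = as.integer(min_support))
  if (p$k < 1L || p$k > 32L) stop("k must be in 1..32")
  if (p$s < p$k) stop("window length s must be >= k")
  if (p$st < 1L || p$st > p$s) stop("step st must be in 1..s")
  if (p$thr <= 0) stop("thr must be positive")
  if (p$mo < 1) stop("mo must be >= 1")
  if (p$min_support < 0) stop("min_support must be >= 0")
  structure(p, class = "sketch_params")
}

#' @export
print.sketch_params <- function(x, ...) {
  cat(sprintf(
    "sketch_params: k=%d s=%d st=%d thr=%g mo=%g min_support=%d\n",
    x$k, x$s, x$st, x$thr, x$mo, x$min_support))
  invisible(x)
}
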