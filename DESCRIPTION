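Package: readthroughr
Title: Detection of Read-Through (Conjoined-Gene) Transcripts from Long Reads
Version: 0.1.0
Authors@R: person("Readthroughr", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies read-through (conjoined-gene) transcripts from long,
    error-prone sequencing reads. The genome is partitioned into isolated
    active regions (IARs) of consecutively ordered genes, each region is
    sketched with sliding-window minimizers under a bijective avalanche hash
    and stored in a contiguous slot-array index, and reads are screened and
    confirmed for evidence spanning two adjacent genes. Downstream tools
    predict whether a read-through transcript is prone to nonsense-mediated
    decay via the 55-nt exon-junction rule and export splice patterns as
    BED12. A synthetic-data module simulates toy genomes, read-through
    isoforms and noisy long reads with truth labels for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
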