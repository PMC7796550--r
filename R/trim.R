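## Adapter trimming and depth normalisation.

#' Remove 3' adapters and length-filter reads
#'
#' For each read the insert is everything left of the adapter match.  A
#' match is either the leftmost exact occurrence of the full adapter, or,
#' failing that, the longest adapter prefix (at least `minOverlap` nt) that
#' ends flush with the read's 3' end -- the partial-adapter situation when
#' the insert plus adapter overruns the read length.  Matching is exact;
#' simulated data appends adapters verbatim and no mismatch tolerance is
#' modelled.
#'
#' @param reads named DNAStringSet (or character vector) of raw reads.
#' @param adapter 3' adapter sequence (DNA).
#' @param minOverlap minimum adapter prefix length accepted at the read end.
#' @param minLen,maxLen insert length bounds; inserts outside
#'   \[minLen, maxLen\] are dropped.
#' @param allowUntrimmed keep reads with no adapter match (length-filtered
#'   but otherwise untouched)?
#' @return DNAStringSet of retained inserts.
#' @examples
#' reads <- c(r1 = paste0(strrep("ACGT", 5), "TGGAATTCTCGG"))
#' trimAdapter(reads, adapter = "TGGAATTCTCGGGTGCCAAGG")
#' @export
trimAdapter <- function(reads, adapter, minOverlap = 8L, minLen = 15L,
                        maxLen = 31L, allowUntrimmed = FALSE) {
    if (missing(adapter) || !nzchar(adapter))
        stop("a non-empty adapter sequence is required")
    if (minLen > maxLen) stop("minLen must be <= maxLen")
    reads <- as_reads(reads)
    seqs <- as.character(reads)
    la <- nchar(adapter)
    # leftmost full-adapter occurrence
    cut <- vapply(seqs, function(s) {
        hit <- regexpr(adapter, s, fixed = TRUE)
        as.integer(hit)
    }, integer(1), USE.NAMES = FALSE)
    # longest end-anchored adapter prefix for the rest
    need <- cut < 0L
    lens <- nchar(seqs)
    kmax <- if (any(need)) min(la - 1L, max(lens[need])) else 0L
    if (kmax >= minOverlap) {
        for (k in seq(kmax, minOverlap)) {   # longest prefix wins
            if (!any(need)) break
            pre <- substr(adapter, 1L, k)
            idx <- which(need & lens >= k)
            if (!length(idx)) next
            hit <- substr(seqs[idx], lens[idx] - k + 1L, lens[idx]) == pre
            cut[idx[hit]] <- lens[idx[hit]] - k + 1L
            need[idx[hit]] <- FALSE
        }
    }
    trimmed <- cut > 0L
    ins_len <- ifelse(trimmed, cut - 1L, nchar(seqs))
    keep <- (trimmed | allowUntrimmed) & ins_len >= minLen & ins_len <= maxLen
    out <- subseq(reads[keep], 1L, ins_len[keep])
    out
}

#' Subsample a library to fixed depth
#'
#' Uniform sampling without replacement, for normalising libraries to a
#' common read count before comparison.  Deterministic for a fixed seed and
#' order-preserving.
#'
#' @param reads DNAStringSet.
#' @param n reads to keep; must not exceed the library size (no
#'   resampling).
#' @param seed integer seed.
#' @return DNAStringSet of `n` reads.
#' @export
subsampleReads <- function(reads, n, seed = 1L) {
    reads <- as_reads(reads)
    if (n > length(reads))
        stop(sprintf("cannot subsample %d reads from a library of %d",
                     n, length(reads)))
    if (n == length(reads)) return(reads)
    idx <- with_seed(seed, sort(sample.int(length(reads), n)))
    reads[idx]
}
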