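## Internal helpers shared across modules.

#' Evaluate an expression under a private RNG state
#'
#' Saves and restores `.Random.seed` so that package functions taking an
#' explicit `seed` argument do not disturb the caller's random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single non-missing number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Coerce reads to a named DNAStringSet
#' @noRd
as_reads <- function(reads) {
    if (is.character(reads))
        reads <- Biostrings::DNAStringSet(reads)
    if (!methods::is(reads, "DNAStringSet"))
        stop("reads must be a DNAStringSet or character vector")
    if (is.null(names(reads)))
        names(reads) <- sprintf("read_%06d", seq_along(reads))
    reads
}

#' Validate an alignment GRanges
#'
#' Alignments are plain [GenomicRanges::GRanges] (1-based, closed intervals,
#' the Bioconductor convention) carrying metadata columns `read_id`
#' (character) and `n_placements` (integer, total perfect placements of that
#' read on the reference).
#'
#' @param aln a GRanges.
#' @return the validated GRanges, with `n_placements` defaulted to `NA` if
#'   absent.
#' @noRd
check_alignments <- function(aln) {
    if (!methods::is(aln, "GRanges"))
        stop("alignments must be a GRanges")
    mc <- S4Vectors::mcols(aln)
    if (is.null(mc$read_id))
        stop("alignments must carry a 'read_id' metadata column")
    if (is.null(mc$n_placements))
        S4Vectors::mcols(aln)$n_placements <- rep(NA_integer_, length(aln))
    if (any(strand(aln) == "*"))
        stop("alignments must be stranded (+ or -)")
    aln
}

#' Stable parameter hash for pipeline stage caching
#' @noRd
param_hash <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}

#' @import methods BiocGenerics S4Vectors IRanges GenomicRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#' @importFrom Biostrings DNAStringSet DNAString BStringSet Views
#'   reverseComplement subseq readDNAStringSet writeXStringSet
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats runif rmultinom setNames
#' @importFrom utils read.delim write.table
NULL
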