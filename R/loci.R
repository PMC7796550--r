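## Density-based annotation of small RNA producing loci.

#' Call expressed loci from read density
#'
#' Pools both strands into per-base coverage, keeps maximal runs with depth
#' >= `minDepth`, merges runs separated by at most `mergeDistance` bp, and
#' emits runs strictly longer than `minLength` nt with their read counts
#' (any-overlap assignment: a read touching a locus by >= 1 bp is counted).
#'
#' @param aln alignment GRanges.
#' @param minDepth minimum pooled per-base depth (inclusive, "at least two
#'   read depth").
#' @param minLength loci must be strictly longer than this many nt
#'   ("greater than 40 nucleotides").
#' @param mergeDistance merge runs separated by gaps of at most this many
#'   bp (0 = overlapping/bookended only, the bedtools-merge default).
#' @param perStrand call loci on each strand's own coverage instead of the
#'   pooled coverage.
#' @return GRanges of loci, sorted and disjoint, with metadata `n_reads`,
#'   `reads_per_bp` and `name`; strand is `*` unless `perStrand`.
#' @examples
#' aln <- GenomicRanges::GRanges("c", IRanges::IRanges(c(11, 11),
#'     width = 50), strand = "+", read_id = c("a", "b"), n_placements = 1L)
#' callLoci(aln)
#' @export
callLoci <- function(aln, minDepth = 2L, minLength = 40L,
                     mergeDistance = 0L, perStrand = FALSE) {
    aln <- check_alignments(aln)
    if (!length(aln))
        return(GRanges(n_reads = integer(0), reads_per_bp = numeric(0),
                       name = character(0)))
    call_one <- function(gr, str) {
        cov <- coverage(gr)
        runs <- methods::as(slice(cov, lower = minDepth,
                                  rangesOnly = TRUE), "GRanges")
        runs <- reduce(runs, min.gapwidth = mergeDistance + 1L)
        runs <- runs[width(runs) > minLength]
        if (!length(runs)) return(runs)
        strand(runs) <- str
        S4Vectors::mcols(runs)$n_reads <-
            countOverlaps(runs, gr, ignore.strand = TRUE)
        runs
    }
    if (perStrand) {
        out <- c(call_one(aln[strand(aln) == "+"], "+"),
                 call_one(aln[strand(aln) == "-"], "-"))
    } else {
        out <- call_one(aln, "*")
    }
    out <- sort(out, ignore.strand = TRUE)
    if (length(out)) {
        S4Vectors::mcols(out)$reads_per_bp <-
            S4Vectors::mcols(out)$n_reads / width(out)
        S4Vectors::mcols(out)$name <- sprintf("locus_%04d", seq_along(out))
    } else {
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            n_reads = integer(0), reads_per_bp = numeric(0),
            name = character(0))
    }
    out
}

#' Per-locus read-length profile
#'
#' Histogram of assigned read lengths per locus (any-overlap assignment: a
#' read overlapping two loci counts in both).  Rows are ordered by
#' descending total read count, the highest-expressing locus first.
#'
#' @param loci GRanges from [callLoci()].
#' @param aln alignment GRanges.
#' @param sizeRange integer(2) read-length bounds of the columns.
#' @param log1p apply `log1p` to the counts.
#' @return numeric matrix (locus x read length), rownames = locus names.
#' @export
locusSizeProfile <- function(loci, aln, sizeRange = c(15L, 31L),
                             log1p = FALSE) {
    aln <- check_alignments(aln)
    sizes <- sizeRange[1]:sizeRange[2]
    m <- matrix(0, length(loci), length(sizes),
                dimnames = list(S4Vectors::mcols(loci)$name, sizes))
    hits <- findOverlaps(loci, aln, ignore.strand = TRUE)
    if (length(hits)) {
        w <- width(aln)[subjectHits(hits)]
        ok <- w >= sizeRange[1] & w <= sizeRange[2]
        tab <- table(factor(queryHits(hits)[ok], levels = seq_along(loci)),
                     factor(w[ok], levels = sizes))
        m <- m + unclass(tab)
        dimnames(m) <- list(S4Vectors::mcols(loci)$name, sizes)
    }
    m <- m[order(rowSums(m), decreasing = TRUE), , drop = FALSE]
    if (log1p) m <- log1p(m)
    m
}

#' Intersect two locus sets
#'
#' Any-overlap (>= 1 bp) interval intersection on matching contigs; each
#' locus of A is counted once however many B loci it touches.
#'
#' @param setA,setB GRanges of loci.
#' @return list with `A_only`, `B_only`, `shared` (loci of A touching any
#'   B locus), and `pct_A_not_in_B` (percentage of A loci with no overlap
#'   in B).
#' @export
intersectLoci <- function(setA, setB) {
    hitsA <- countOverlaps(setA, setB, ignore.strand = TRUE) > 0L
    hitsB <- countOverlaps(setB, setA, ignore.strand = TRUE) > 0L
    list(A_only = sum(!hitsA), B_only = sum(!hitsB), shared = sum(hitsA),
         pct_A_not_in_B = if (length(setA))
             100 * sum(!hitsA) / length(setA) else NA_real_)
}
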