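## piRNA ping-pong and nucleotide-bias signatures.
##
## Piwi slicing cuts a target 10 nt from the 5' end of the guide piRNA, so
## ping-pong amplification over-represents opposite-strand read pairs whose
## 5' ends overlap by exactly 10 nt, with a 5' U bias on primary piRNAs and
## an A at position 10 of secondaries.

#' 5'-5' opposite-strand overlap histogram
#'
#' For every (+, -) alignment pair on the same contig the 5' overlap is
#' o = (5' position of the minus read) - (5' position of the plus read) + 1,
#' i.e. o = 10 means the two 5' ends share positions p..p+9.  Pairs are
#' counted for o in 1..`maxOffset`; the z-score at each offset compares its
#' count with the mean and standard deviation of all the other offsets.
#'
#' @param aln stranded alignment GRanges.
#' @param maxOffset largest offset tallied.
#' @return an [OverlapHistogram-class].
#' @export
fivePrimeOverlapHist <- function(aln, maxOffset = 30L) {
    aln <- check_alignments(aln)
    offs <- seq_len(maxOffset)
    cnt <- setNames(numeric(maxOffset), offs)
    for (ctg in unique(as.character(seqnames(aln)))) {
        sel <- as.character(seqnames(aln)) == ctg
        p5 <- start(aln)[sel & as.character(strand(aln)) == "+"]
        m5 <- end(aln)[sel & as.character(strand(aln)) == "-"]
        if (!length(p5) || !length(m5)) next
        tp <- table(p5)
        tm <- table(m5)
        ppos <- as.integer(names(tp))
        for (o in offs) {
            hit <- match(as.character(ppos + o - 1L), names(tm))
            ok <- !is.na(hit)
            if (any(ok))
                cnt[o] <- cnt[o] +
                    sum(as.numeric(tp[ok]) * as.numeric(tm[hit[ok]]))
        }
    }
    z <- vapply(offs, function(o) {
        rest <- cnt[-o]
        s <- sd(rest)
        if (is.na(s) || s == 0) return(NA_real_)
        (cnt[o] - mean(rest)) / s
    }, numeric(1))
    new("OverlapHistogram", counts = cnt,
        zscores = setNames(z, offs))
}

#' Positional nucleotide composition of reads
#'
#' Computes per-position base frequencies on the read-sense sequence over
#' the 5'-most `N` positions.  Accepts either a DNAStringSet of reads or an
#' alignment GRanges plus the genome, in which case the read-sense sequence
#' of each (optionally strand-filtered) alignment is extracted (reverse
#' complement of the genomic slice for minus-strand alignments).  Reads
#' shorter than `N` contribute only to the positions they cover.
#'
#' @param x DNAStringSet of reads, or alignment GRanges.
#' @param N positions from the 5' end.
#' @param genome named DNAStringSet; required when `x` is a GRanges.
#' @param strandFilter optional `"+"` or `"-"`; keep only alignments on
#'   that strand (ignored for sequence input).
#' @return a [PositionFrequencyMatrix-class].
#' @export
nucleotideBias <- function(x, N = 20L, genome = NULL, strandFilter = NULL) {
    if (is(x, "GRanges")) {
        if (is.null(genome))
            stop("genome is required to extract sequences from alignments")
        x <- check_alignments(x)
        if (!is.null(strandFilter))
            x <- x[as.character(strand(x)) == strandFilter]
        seqs <- DNAStringSet()
        for (ctg in unique(as.character(seqnames(x)))) {
            sel <- as.character(seqnames(x)) == ctg
            seqs <- c(seqs, .slice_seqs(genome[[ctg]], start(x)[sel],
                                        end(x)[sel],
                                        as.character(strand(x))[sel]))
        }
    } else {
        seqs <- as_reads(x)
    }
    bases <- c("A", "C", "G", "T")
    cnts <- matrix(0L, 4L, N, dimnames = list(bases, seq_len(N)))
    if (length(seqs)) {
        chars <- as.character(seqs)
        lens <- nchar(chars)
        for (p in seq_len(N)) {
            b <- substr(chars[lens >= p], p, p)
            tb <- table(factor(b, levels = bases))
            cnts[, p] <- cnts[, p] + as.integer(tb)
        }
    }
    tot <- colSums(cnts)
    freq <- sweep(cnts, 2L, pmax(tot, 1L), "/")
    new("PositionFrequencyMatrix", freq = freq, baseCounts = cnts,
        nReads = length(seqs))
}

#' Strand composition of an alignment set
#'
#' @param aln alignment GRanges.
#' @param region optional GRanges; only alignments intersecting it by at
#'   least 1 bp are counted (any-overlap semantics).
#' @return list with `plus` and `minus` percentages (summing to 100 when
#'   any alignment is counted), `n`, and `empty` flag (`plus`/`minus` are 0
#'   when no alignment is in scope).
#' @export
strandFraction <- function(aln, region = NULL) {
    aln <- check_alignments(aln)
    if (!is.null(region))
        aln <- aln[countOverlaps(aln, region, ignore.strand = TRUE) > 0L]
    n <- length(aln)
    if (n == 0L)
        return(list(plus = 0, minus = 0, n = 0L, empty = TRUE))
    np <- sum(as.character(strand(aln)) == "+")
    list(plus = 100 * np / n, minus = 100 * (n - np) / n, n = n,
         empty = FALSE)
}
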