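## Dicer cleavage signature: the overlap-pair matrix.
##
## RNase III cleavage of dsRNA leaves duplexes whose strands overlap by
## 2 nt less than their length (2-nt 3' overhangs).  An ordered pair
## (query alignment, opposite-strand partner on the same contig) is counted
## when the genomic overlap equals query length - overhang.  "literal" mode
## applies only this overlap-length rule, as stated for the original
## analysis; "canonical" mode additionally requires the register of a true
## duplex (partner 5' end `overhang` nt inside the query 3' end), because
## the literal rule also admits a mirror register.

## Core pair scan.  Returns a data.frame of ordered pairs with indices into
## `aln` plus query/partner lengths.
.dicerPairs <- function(aln, sizeRange = c(15L, 31L), overhang = 2L,
                        mode = c("literal", "canonical"),
                        deduplicate = FALSE) {
    mode <- match.arg(mode)
    aln <- check_alignments(aln)
    if (deduplicate && length(aln))
        aln <- aln[!duplicated(S4Vectors::mcols(aln)$read_id)]
    w <- width(aln)
    sub <- which(w >= sizeRange[1] & w <= sizeRange[2])
    a <- aln[sub]
    wa <- w[sub]
    str <- as.character(strand(a))
    st <- start(a); en <- end(a)
    out <- list()
    for (qlen in sort(unique(wa))) {
        v <- qlen - overhang
        if (v < 1L) next
        qsel <- which(wa == qlen)
        hits <- findOverlaps(a[qsel], a, minoverlap = v,
                             ignore.strand = TRUE)
        if (!length(hits)) next
        qh <- qsel[queryHits(hits)]
        sh <- subjectHits(hits)
        keep <- str[qh] != str[sh]
        ovl <- pmin(en[qh], en[sh]) - pmax(st[qh], st[sh]) + 1L
        keep <- keep & ovl == v
        if (mode == "canonical") {
            reg <- ifelse(str[qh] == "+",
                          en[sh] == en[qh] - overhang,
                          st[sh] == st[qh] + overhang)
            keep <- keep & reg
        }
        if (!any(keep)) next
        out[[as.character(qlen)]] <- data.frame(
            query = sub[qh[keep]], partner = sub[sh[keep]],
            qlen = qlen, plen = wa[sh[keep]])
    }
    if (!length(out))
        return(data.frame(query = integer(0), partner = integer(0),
                          qlen = integer(0), plen = integer(0)))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Count Dicer duplex read pairs by size
#'
#' Builds the (query length x partner length) matrix of opposite-strand
#' alignment pairs satisfying the Dicer overlap criterion: genomic overlap
#' = query length - `overhang`.  Each ordered pair increments one cell, so
#' the matrix is asymmetric when the two strands of a duplex differ in
#' length (a pair offset by one or two bases is counted at (q, t) but not
#' necessarily at (t, q)).
#'
#' @param aln alignment GRanges (metadata `read_id`, `n_placements`);
#'   alignments on all contigs are scanned, pairs never span contigs.
#' @param sizeRange integer(2); alignments outside it are ignored.
#' @param overhang Dicer 3' overhang in nt.
#' @param mode `"literal"` (overlap rule only, default) or `"canonical"`
#'   (duplex register also required).
#' @param deduplicate count each read id at its first placement only,
#'   instead of once per aligned instance.
#' @return a [PairMatrix-class].
#' @examples
#' aln <- GenomicRanges::GRanges("c", IRanges::IRanges(c(101, 99),
#'     width = 21), strand = c("+", "-"),
#'     read_id = c("a", "b"), n_placements = 1L)
#' counts(pairMatrix(aln))["21", "21"]
#' @export
pairMatrix <- function(aln, sizeRange = c(15L, 31L), overhang = 2L,
                       mode = c("literal", "canonical"),
                       deduplicate = FALSE) {
    mode <- match.arg(mode)
    sizeRange <- as.integer(sizeRange)
    pairs <- .dicerPairs(aln, sizeRange, overhang, mode, deduplicate)
    sizes <- sizeRange[1]:sizeRange[2]
    m <- matrix(0L, length(sizes), length(sizes),
                dimnames = list(query = sizes, partner = sizes))
    if (nrow(pairs)) {
        tab <- table(factor(pairs$qlen, levels = sizes),
                     factor(pairs$plen, levels = sizes))
        m <- m + unclass(tab)
        dimnames(m) <- list(query = sizes, partner = sizes)
    }
    new("PairMatrix", counts = m, sizeRange = sizeRange,
        overhang = as.integer(overhang), mode = mode,
        nAlignments = length(aln))
}

#' Fraction of reads showing the Dicer duplex signature
#'
#' The fraction of distinct mapped reads that participate in at least one
#' counted Dicer pair (as query or as partner), over all distinct mapped
#' reads in the alignment set.
#'
#' @inheritParams pairMatrix
#' @return numeric in \[0, 1\] (NA for an empty alignment set).
#' @export
dicerReadFraction <- function(aln, sizeRange = c(15L, 31L), overhang = 2L,
                              mode = c("literal", "canonical"),
                              deduplicate = FALSE) {
    mode <- match.arg(mode)
    aln <- check_alignments(aln)
    if (!length(aln)) return(NA_real_)
    pairs <- .dicerPairs(aln, as.integer(sizeRange), overhang, mode,
                         deduplicate)
    ids <- S4Vectors::mcols(aln)$read_id
    paired <- unique(ids[c(pairs$query, pairs$partner)])
    length(paired) / length(unique(ids))
}

#' Dicer signature enrichment between library conditions
#'
#' Ratio of the Dicer read fraction in a condition of interest to that of a
#' total-RNA reference library, i.e. how strongly the condition enriches
#' reads bearing the 2-nt overhang signature.
#'
#' @param fractionCondition,fractionTotal Dicer read fractions.
#' @return `fractionCondition / fractionTotal`.
#' @export
dicerEnrichment <- function(fractionCondition, fractionTotal) {
    if (is.na(fractionTotal) || fractionTotal == 0)
        stop("enrichment undefined: total-RNA Dicer fraction is zero")
    fractionCondition / fractionTotal
}

#' Fraction of reads in the siRNA size range
#'
#' @param aln alignment GRanges.
#' @param lo,hi inclusive length bounds (19-23 nt, arthropod Dicer
#'   products).
#' @return fraction of distinct mapped reads with length in \[lo, hi\].
#' @export
sirnaSizeFraction <- function(aln, lo = 19L, hi = 23L) {
    aln <- check_alignments(aln)
    if (!length(aln)) return(NA_real_)
    first <- !duplicated(S4Vectors::mcols(aln)$read_id)
    w <- width(aln)[first]
    mean(w >= lo & w <= hi)
}
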