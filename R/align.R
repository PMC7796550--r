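## Self-contained perfect-match, all-placements short read aligner.
##
## Semantics replicate `bowtie -a -v0 -m N`: every exact full-length
## placement on either strand is reported, and a read with more than
## `maxPlacements` placements is discarded entirely (the -m cap, which in
## practice removes extremely low-complexity reads).  A k-mer seed table
## plus full-length verification makes `k` a speed knob only; the placement
## set is identical to a naive string search.

#' Build a k-mer seed index over a reference
#'
#' @param x named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param k seed length; must not exceed the shortest read that will be
#'   queried.
#' @return a [GenomeIndex-class].
#' @examples
#' idx <- buildIndex(Biostrings::DNAStringSet(c(chr = strrep("ACGT", 30))))
#' idx
#' @export
buildIndex <- function(x, k = 12L) {
    if (is.character(x) && length(x) == 1L)
        x <- readDNAStringSet(x)
    if (!is(x, "DNAStringSet")) stop("x must be a DNAStringSet or FASTA path")
    if (length(x) == 0L) stop("empty reference: no contigs")
    if (is.null(names(x))) stop("reference contigs must be named")
    k <- as.integer(k)
    tab <- new.env(parent = emptyenv(), size = sum(Biostrings::width(x)))
    for (ci in seq_along(x)) {
        s <- as.character(x[[ci]])
        L <- nchar(s)
        if (L < k) next
        starts <- seq_len(L - k + 1L)
        kmers <- substring(s, starts, starts + k - 1L)
        sp <- split(starts, kmers)
        nms <- names(sp)
        for (i in seq_along(sp)) {
            km <- nms[i]
            entry <- cbind(contig = rep.int(ci, length(sp[[i]])),
                           pos = sp[[i]])
            prev <- tab[[km]]
            tab[[km]] <- if (is.null(prev)) entry else rbind(prev, entry)
        }
    }
    new("GenomeIndex", seqs = x, k = k, table = tab)
}

## All exact placements of one sequence (character) on one strand's
## forward text; returns matrix(contig, pos).
.seed_verify <- function(seq, chars, tab, k) {
    cand <- tab[[substr(seq, 1L, k)]]
    if (is.null(cand)) return(NULL)
    len <- nchar(seq)
    ok <- logical(nrow(cand))
    for (ci in unique(cand[, "contig"])) {
        sel <- cand[, "contig"] == ci
        pos <- cand[sel, "pos"]
        inb <- pos + len - 1L <= nchar(chars[ci])
        hit <- inb
        if (any(inb))
            hit[inb] <- substring(chars[ci], pos[inb],
                                  pos[inb] + len - 1L) == seq
        ok[sel] <- hit
    }
    cand[ok, , drop = FALSE]
}

#' Map reads with exact full-length matching on both strands
#'
#' @param reads named DNAStringSet.
#' @param index a [GenomeIndex-class].
#' @param reportAll report every placement (default); if `FALSE` only the
#'   first placement (contig, then coordinate, plus strand first) is kept,
#'   `n_placements` still records the total.
#' @param maxPlacements reads with more perfect placements than this are
#'   discarded entirely (Bowtie `-m` semantics).
#' @return alignment GRanges (`read_id`, `n_placements`), seqlengths set
#'   from the index. Unmapped reads are absent.
#' @export
mapPerfect <- function(reads, index, reportAll = TRUE,
                       maxPlacements = 200L) {
    stopifnot(is(index, "GenomeIndex"))
    reads <- as_reads(reads)
    if (length(reads) == 0L)
        return(.empty_alignments(index))
    short <- Biostrings::width(reads) < index@k
    if (any(short))
        stop("read(s) shorter than the index seed length (k=", index@k,
             "): ", paste(head(names(reads)[short], 3L), collapse = ", "))
    chars <- as.character(index@seqs)
    useqs <- unique(as.character(reads))
    urc <- as.character(reverseComplement(DNAStringSet(useqs)))
    hits <- vector("list", length(useqs))
    for (i in seq_along(useqs)) {
        fwd <- .seed_verify(useqs[i], chars, index@table, index@k)
        rev <- .seed_verify(urc[i], chars, index@table, index@k)
        n <- NROW(fwd) + NROW(rev)
        if (n == 0L || n > maxPlacements) next
        m <- rbind(if (NROW(fwd)) cbind(fwd, strand = 1L),
                   if (NROW(rev)) cbind(rev, strand = 2L))
        if (!reportAll)
            m <- m[order(m[, "contig"], m[, "strand"],
                         m[, "pos"])[1L], , drop = FALSE]
        hits[[i]] <- cbind(m, n_placements = n)
    }
    seq_of <- match(as.character(reads), useqs)
    per_read <- hits[seq_of]
    nh <- vapply(per_read, NROW, integer(1))
    if (sum(nh) == 0L)
        return(.empty_alignments(index))
    all <- do.call(rbind, per_read)
    len <- rep(Biostrings::width(reads), nh)
    gr <- GRanges(names(index@seqs)[all[, "contig"]],
                  IRanges(all[, "pos"], width = len),
                  strand = c("+", "-")[all[, "strand"]],
                  read_id = rep(names(reads), nh),
                  n_placements = all[, "n_placements"])
    seqlengths(gr) <- setNames(
        Biostrings::width(index@seqs), names(index@seqs))[seqlevels(gr)]
    gr
}

.empty_alignments <- function(index) {
    gr <- GRanges(read_id = character(0), n_placements = integer(0))
    GenomeInfoDb::seqlevels(gr) <- names(index@seqs)
    seqlengths(gr) <- setNames(Biostrings::width(index@seqs),
                               names(index@seqs))
    gr
}

#' Two-genome hierarchical mapping statistics
#'
#' Maps reads to genome A, then re-maps the A-mapped reads to genome B with
#' identical settings, reporting what fraction of A-mapped reads also map
#' to B versus map exclusively to A.  Used to ask how many putatively
#' plant-derived reads could instead originate from the consumer's own
#' genome.
#'
#' @param reads named DNAStringSet.
#' @param indexA,indexB [GenomeIndex-class] objects (stage 1 and stage 2).
#' @param ... passed to [mapPerfect()].
#' @return list with `fractionA` (reads mapping to A / all reads),
#'   `coMapped` and `exclusiveA` (fractions over A-mapped reads), read
#'   counts, and the two alignment sets.
#' @export
hierarchicalMap <- function(reads, indexA, indexB, ...) {
    reads <- as_reads(reads)
    alnA <- mapPerfect(reads, indexA, ...)
    idsA <- unique(S4Vectors::mcols(alnA)$read_id)
    alnB <- if (length(idsA))
        mapPerfect(reads[idsA], indexB, ...) else .empty_alignments(indexB)
    idsB <- unique(S4Vectors::mcols(alnB)$read_id)
    nA <- length(idsA)
    list(fractionA = if (length(reads)) nA / length(reads) else NA_real_,
         coMapped = if (nA) length(idsB) / nA else NA_real_,
         exclusiveA = if (nA) 1 - length(idsB) / nA else NA_real_,
         nReads = length(reads), nAmapped = nA, nCoMapped = length(idsB),
         alignmentsA = alnA, alignmentsB = alnB)
}
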