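## File-format boundary.  Internals are 1-based closed GRanges; BED and the
## truth TSV are written 0-based half-open, SAM 1-based, as their formats
## require.

#' Write reads as FASTQ
#'
#' Four-line records with a constant quality string ("I"); the pipeline
#' never consumes qualities.
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLibrary <- function(reads, path) {
    reads <- as_reads(reads)
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    writeXStringSet(reads, path, format = "fastq", qualities = qual)
    invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' @param path FASTQ file.
#' @return named DNAStringSet (identifier up to the first whitespace).
#' @export
readLibrary <- function(path) {
    readDNAStringSet(path, format = "fastq", with.qualities = FALSE)
}

#' Write / read simulator ground truth
#'
#' Tab-separated, one row per read: `read_id`, `class`, `contig`, `start`,
#' `end` (0-based half-open in the file, BED-style), `strand`, `partner`.
#'
#' @param truth data.frame as produced by the simulate functions (1-based
#'   closed coordinates in memory).
#' @param path file path.
#' @return `path` invisibly / the truth data.frame (1-based closed).
#' @export
writeTruth <- function(truth, path) {
    out <- truth
    out$start <- out$start - 1L   # to 0-based half-open
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    tr <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(partner = "character"))
    tr$start <- tr$start + 1L     # back to 1-based closed
    tr
}

#' Convert a truth table to alignment-style GRanges
#'
#' @param truth truth data.frame (1-based closed).
#' @param seqlengths optional named contig lengths.
#' @return GRanges with `read_id` and `n_placements = 1` metadata, usable
#'   wherever alignments are expected.
#' @export
truthToGRanges <- function(truth, seqlengths = NULL) {
    gr <- GRanges(truth$contig, IRanges(truth$start, truth$end),
                  strand = truth$strand, read_id = truth$read_id,
                  n_placements = 1L)
    if (!is.null(seqlengths))
        seqlengths(gr) <- seqlengths[seqlevels(gr)]
    gr
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM: FLAG carries only the strand bit (16 for minus),
#' CIGAR is full-length match, and the placement count is stored in the
#' `NH` tag.  SEQ is emitted in reference-forward orientation when read
#' sequences are supplied.
#'
#' @param aln alignment GRanges (`read_id`, `n_placements` metadata);
#'   `seqlengths` must be set for the `@SQ` header.
#' @param path output file.
#' @param reads optional named DNAStringSet of read-sense sequences.
#' @return `path`, invisibly.
#' @export
writeSAM <- function(aln, path, reads = NULL) {
    aln <- check_alignments(aln)
    sl <- seqlengths(aln)
    if (anyNA(sl))
        stop("seqlengths must be set on the alignments to write SAM")
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    seq_field <- rep("*", length(aln))
    if (!is.null(reads) && length(aln)) {
        reads <- as_reads(reads)
        s <- reads[S4Vectors::mcols(aln)$read_id]
        neg <- as.character(strand(aln)) == "-"
        if (any(neg)) s[neg] <- reverseComplement(s[neg])
        seq_field <- as.character(s)
    }
    np <- S4Vectors::mcols(aln)$n_placements
    np[is.na(np)] <- 1L
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                    S4Vectors::mcols(aln)$read_id,
                    ifelse(as.character(strand(aln)) == "-", 16L, 0L),
                    as.character(seqnames(aln)), start(aln), width(aln),
                    seq_field, np)
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a SAM file into alignment GRanges
#'
#' Parses plain-text single-end SAM with match-only CIGARs (the output of
#' [writeSAM()] or of a perfect-match external aligner); unmapped records
#' are dropped.
#'
#' @param path SAM file.
#' @return alignment GRanges with `read_id` and `n_placements` (from the
#'   `NH` tag when present) and seqlengths from the header.
#' @export
readSAM <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "@")]
    body <- lines[!startsWith(lines, "@") & nzchar(lines)]
    sq <- hdr[startsWith(hdr, "@SQ")]
    sl <- integer(0)
    if (length(sq)) {
        sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
        ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
        sl <- setNames(ln, sn)
    }
    if (!length(body)) {
        gr <- GRanges(read_id = character(0), n_placements = integer(0))
        if (length(sl)) seqlengths(gr) <- sl
        return(gr)
    }
    f <- strsplit(body, "\t", fixed = TRUE)
    flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
    keep <- bitwAnd(flag, 4L) == 0L
    f <- f[keep]; flag <- flag[keep]
    pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
    cigar <- vapply(f, `[[`, character(1), 6L)
    if (any(grepl("[^0-9M]", cigar)))
        stop("only match-only CIGARs are supported")
    len <- as.integer(sub("M", "", cigar, fixed = TRUE))
    nh <- vapply(f, function(x) {
        tag <- grep("^NH:i:", x[-(1:11)], value = TRUE)
        if (length(tag)) as.integer(sub("NH:i:", "", tag[1])) else NA_integer_
    }, integer(1))
    gr <- GRanges(vapply(f, `[[`, character(1), 3L),
                  IRanges(pos, width = len),
                  strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                  read_id = vapply(f, `[[`, character(1), 1L),
                  n_placements = nh)
    if (length(sl)) seqlengths(gr) <- sl[seqlevels(gr)]
    gr
}

#' Write / read BED6
#'
#' Thin wrappers over [rtracklayer::export()] / [rtracklayer::import()]
#' mapping `read_id` to the BED name field and `n_placements` to the score.
#'
#' @param gr alignment (or locus) GRanges.
#' @param path BED file.
#' @export
writeBed <- function(gr, path) {
    out <- gr
    mc <- S4Vectors::mcols(out)
    nm <- if (!is.null(mc$read_id)) mc$read_id else
          if (!is.null(mc$name)) mc$name else
          sprintf("feature_%d", seq_along(out))
    sc <- if (!is.null(mc$n_placements)) mc$n_placements else
          if (!is.null(mc$score)) mc$score else 0L
    sc[is.na(sc)] <- 0L
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = nm,
                                                  score = as.numeric(sc))
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    mc <- S4Vectors::mcols(gr)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        read_id = as.character(mc$name),
        n_placements = as.integer(mc$score))
    gr
}

#' Write a pair matrix as TSV
#'
#' Rows are query lengths, columns partner lengths.
#'
#' @param pm a [PairMatrix-class].
#' @param path output file.
#' @export
writePairMatrix <- function(pm, path) {
    stopifnot(is(pm, "PairMatrix"))
    df <- data.frame(query_length = rownames(pm@counts), pm@counts,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
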