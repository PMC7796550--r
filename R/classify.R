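## Read-class accounting: size distributions and annotation overlap.

#' Read-length histogram
#'
#' @param x DNAStringSet of reads, or alignment GRanges (one length per
#'   distinct read id).
#' @param sizeRange integer(2) length bounds of the histogram; reads
#'   outside it are ignored.
#' @return a [SizeDistribution-class].
#' @export
sizeDistribution <- function(x, sizeRange = c(15L, 31L)) {
    if (is(x, "GRanges")) {
        x <- check_alignments(x)
        lens <- width(x)[!duplicated(S4Vectors::mcols(x)$read_id)]
    } else {
        lens <- Biostrings::width(as_reads(x))
    }
    sizes <- sizeRange[1]:sizeRange[2]
    lens <- lens[lens >= sizeRange[1] & lens <= sizeRange[2]]
    cnt <- table(factor(lens, levels = sizes))
    new("SizeDistribution",
        counts = setNames(as.numeric(cnt), sizes),
        total = length(lens))
}

#' Classify reads by annotation overlap
#'
#' Any-overlap assignment of alignments to annotation classes; a read
#' overlapping several classes is resolved by the priority order (first
#' match wins), and reads touching no annotation fall into `other`.
#' Classification is per distinct read id (a read's best class over all
#' its placements).
#'
#' @param aln alignment GRanges.
#' @param annotations GRanges with a `class` metadata column.
#' @param priority class priority order, highest first.
#' @return list with `counts` and `fractions` per class (including
#'   `other`), `n` distinct reads, and the priority used.
#' @export
annotateReads <- function(aln, annotations,
                          priority = c("miRNA", "tRNA", "rRNA")) {
    aln <- check_alignments(aln)
    if (is.null(S4Vectors::mcols(annotations)$class))
        stop("annotations must carry a 'class' metadata column")
    cls <- as.character(S4Vectors::mcols(annotations)$class)
    extra <- setdiff(unique(cls), priority)
    order_all <- c(priority, sort(extra))
    ids <- S4Vectors::mcols(aln)$read_id
    uids <- unique(ids)
    rank <- rep.int(length(order_all) + 1L, length(uids))  # default: other
    hits <- findOverlaps(aln, annotations, ignore.strand = TRUE)
    if (length(hits)) {
        r <- match(cls[subjectHits(hits)], order_all)
        i <- match(ids[queryHits(hits)], uids)
        best <- tapply(r, i, min)
        rank[as.integer(names(best))] <- pmin(
            rank[as.integer(names(best))], as.integer(best))
    }
    levels_all <- c(order_all, "other")
    assigned <- factor(levels_all[rank], levels = levels_all)
    cnt <- table(assigned)
    list(counts = setNames(as.integer(cnt), levels_all),
         fractions = setNames(as.numeric(cnt) / max(1L, length(uids)),
                              levels_all),
         n = length(uids), priority = order_all)
}

#' Class representation ratio between two libraries
#'
#' Ratio of a class's library fraction in A to that in B, e.g. a value of 3
#' means miRNAs are three times better represented in library A.
#'
#' @param classA,classB outputs of [annotateReads()] (or named fraction
#'   vectors).
#' @param class class name to compare.
#' @return numeric ratio.
#' @export
representationRatio <- function(classA, classB, class = "miRNA") {
    frac <- function(x) {
        if (is.list(x) && !is.null(x$fractions)) x$fractions[[class]]
        else x[[class]]
    }
    fa <- frac(classA)
    fb <- frac(classB)
    if (is.na(fb) || fb == 0)
        stop("representation ratio undefined: class absent from library B")
    fa / fb
}
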