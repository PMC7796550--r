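## Strand-resolved coverage analytics.

#' Build a strand-resolved coverage profile
#'
#' Each kept alignment increments its strand's per-base depth over its
#' interval.  Multi-mapped reads contribute at every placement (consistent
#' with all-placements mapping); `weighted = TRUE` divides each placement's
#' contribution by its `n_placements` instead.
#'
#' @param aln alignment GRanges with seqlengths set for `contig` (or pass
#'   `contigLength`).
#' @param contig contig to profile.
#' @param contigLength explicit contig length (bp), overriding seqlengths.
#' @param sizeRange optional integer(2); keep only alignments with read
#'   length inside it.
#' @param uniqueness `"all"`, `"unique"` (n_placements == 1) or `"multi"`
#'   (n_placements > 1).
#' @param maxPlacements optional cap; drop alignments of reads with more
#'   placements.
#' @param weighted divide depth contributions by `n_placements`.
#' @return a [CoverageProfile-class].
#' @export
buildCoverage <- function(aln, contig, contigLength = NULL,
                          sizeRange = NULL,
                          uniqueness = c("all", "unique", "multi"),
                          maxPlacements = NULL, weighted = FALSE) {
    uniqueness <- match.arg(uniqueness)
    aln <- check_alignments(aln)
    if (is.null(contigLength)) {
        contigLength <- seqlengths(aln)[contig]
        if (is.na(contigLength))
            stop("contig length unknown: set seqlengths or pass ",
                 "contigLength")
    }
    contigLength <- as.integer(contigLength)
    keep <- as.character(seqnames(aln)) == contig
    filters <- list(contig = contig)
    if (!is.null(sizeRange)) {
        keep <- keep & width(aln) >= sizeRange[1] &
            width(aln) <= sizeRange[2]
        filters$sizeRange <- sizeRange
    }
    np <- S4Vectors::mcols(aln)$n_placements
    if (uniqueness == "unique") keep <- keep & !is.na(np) & np == 1L
    if (uniqueness == "multi") keep <- keep & !is.na(np) & np > 1L
    filters$uniqueness <- uniqueness
    if (!is.null(maxPlacements)) {
        keep <- keep & (is.na(np) | np <= maxPlacements)
        filters$maxPlacements <- maxPlacements
    }
    filters$weighted <- weighted
    a <- aln[keep]
    depth_of <- function(gr) {
        if (!length(gr)) return(Rle(0, contigLength))
        ir <- IRanges(start(gr), end(gr))
        if (weighted)
            coverage(ir, width = contigLength,
                     weight = 1 / S4Vectors::mcols(gr)$n_placements)
        else coverage(ir, width = contigLength)
    }
    new("CoverageProfile", contig = contig,
        plus = depth_of(a[strand(a) == "+"]),
        minus = depth_of(a[strand(a) == "-"]),
        filters = filters)
}

#' Dual- versus single-strand coverage partition
#'
#' Classifies every reference base as dual-covered (depth > 0 on both
#' strands -- the footprint of a double-stranded substrate), single-strand
#' covered, or uncovered.  The three fractions sum to 1 exactly.
#'
#' @param profile a [CoverageProfile-class].
#' @return list with `dual`, `single`, `uncovered` fractions of the contig.
#' @export
dualStrandFraction <- function(profile) {
    stopifnot(is(profile, "CoverageProfile"))
    L <- length(profile@plus)
    p <- profile@plus > 0
    m <- profile@minus > 0
    dual <- sum(p & m)
    single <- sum(xor(p, m))
    list(dual = dual / L, single = single / L,
         uncovered = (L - dual - single) / L)
}

#' Length-normalised compartment representation ratio
#'
#' Compares read density (distinct mapped reads per bp) between two genome
#' compartments, e.g. plastid versus nuclear: values above 1 mean the
#' plastid is over-represented relative to its size.  Reads mapping to both
#' compartments are counted in both; their number is reported.
#'
#' @param aln alignment GRanges covering both compartments.
#' @param compartmentLengths named numeric with entries for `numerator` and
#'   `denominator`.
#' @param numerator,denominator contig/compartment names (defaults
#'   `"plastid"` and `"nuclear"`).
#' @return list with `ratio`, per-compartment read counts and densities,
#'   and `n_shared` (reads mapping to both).
#' @export
compartmentRatio <- function(aln, compartmentLengths,
                             numerator = "plastid",
                             denominator = "nuclear") {
    aln <- check_alignments(aln)
    ids_num <- unique(S4Vectors::mcols(aln)$read_id[
        as.character(seqnames(aln)) == numerator])
    ids_den <- unique(S4Vectors::mcols(aln)$read_id[
        as.character(seqnames(aln)) == denominator])
    if (!length(ids_den))
        stop("ratio undefined: no reads map to the denominator compartment")
    dens_num <- length(ids_num) / compartmentLengths[[numerator]]
    dens_den <- length(ids_den) / compartmentLengths[[denominator]]
    list(ratio = dens_num / dens_den,
         n_numerator = length(ids_num), n_denominator = length(ids_den),
         density_numerator = dens_num, density_denominator = dens_den,
         n_shared = length(intersect(ids_num, ids_den)))
}

#' Windowed density track
#'
#' Tiling-window sums of a strand's depth vector, for export or plotting.
#'
#' @param profile a [CoverageProfile-class].
#' @param window window width in bp (the final window may be shorter).
#' @param strand `"+"`, `"-"` or `"both"` (pooled).
#' @param normalize `"none"` or `"max"` (scale so the peak is 1).
#' @return data.frame with `start`, `end` (1-based closed) and `density`.
#' @export
densityTrack <- function(profile, window = 50L,
                         strand = c("both", "+", "-"),
                         normalize = c("none", "max")) {
    stopifnot(is(profile, "CoverageProfile"))
    strand <- match.arg(strand)
    normalize <- match.arg(normalize)
    depth <- switch(strand,
                    "+" = profile@plus,
                    "-" = profile@minus,
                    both = profile@plus + profile@minus)
    L <- length(depth)
    starts <- seq.int(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    v <- as.numeric(depth)
    dens <- vapply(seq_along(starts),
                   function(i) sum(v[starts[i]:ends[i]]), numeric(1))
    if (normalize == "max" && any(dens > 0)) dens <- dens / max(dens)
    data.frame(start = starts, end = ends, density = dens)
}

#' Export a coverage profile as bedGraph (one file per strand)
#'
#' @param profile a [CoverageProfile-class].
#' @param prefix output path prefix; files `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph` are written.
#' @return the two paths, invisibly.
#' @export
writeBedGraph <- function(profile, prefix) {
    stopifnot(is(profile, "CoverageProfile"))
    paths <- character(2)
    for (i in 1:2) {
        str <- c("+", "-")[i]
        depth <- if (str == "+") profile@plus else profile@minus
        rl <- S4Vectors::runLength(depth)
        ends <- cumsum(rl)
        cov <- GRanges(profile@contig,
                       IRanges(ends - rl + 1L, ends),
                       score = as.numeric(S4Vectors::runValue(depth)))
        seqlengths(cov) <- setNames(length(depth), profile@contig)
        paths[i] <- paste0(prefix, if (str == "+") ".plus" else ".minus",
                           ".bedGraph")
        rtracklayer::export(cov, paths[i], format = "bedGraph")
    }
    invisible(paths)
}
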