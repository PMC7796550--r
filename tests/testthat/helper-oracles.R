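## Shared fixtures and independent brute-force oracles.  Oracles are kept
## deliberately naive (full scans, quadratic loops, per-base vectors) so
## they cannot share a defect with the implementations they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(S4Vectors)
    library(IRanges)
})

## Convenience alignment constructor (1-based closed).
aln_gr <- function(start, width, strand, contig = "chr",
                   id = sprintf("r%03d", seq_along(start)),
                   seqlen = NULL) {
    gr <- GRanges(contig, IRanges(start, width = width), strand = strand,
                  read_id = id, n_placements = 1L)
    if (!is.null(seqlen))
        seqlengths(gr) <- setNames(as.integer(seqlen),
                                   seqlevels(gr))
    gr
}

random_genome <- function(len, seed = 1, name = "chr") {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    setNames(DNAStringSet(s), name)
}

## Oracle 1: naive full-scan exact mapping (Biostrings matchPattern),
## including the -m discard cap.
oracle_map <- function(reads, genome, maxPlacements = 200L) {
    rows <- list()
    for (i in seq_along(reads)) {
        seq <- reads[[i]]
        hits <- list()
        for (ctg in names(genome)) {
            fwd <- start(Biostrings::matchPattern(seq, genome[[ctg]]))
            rev <- start(Biostrings::matchPattern(Biostrings::reverseComplement(seq),
                                      genome[[ctg]]))
            if (length(fwd))
                hits[[length(hits) + 1L]] <- data.frame(
                    contig = ctg, start = fwd, strand = "+")
            if (length(rev))
                hits[[length(hits) + 1L]] <- data.frame(
                    contig = ctg, start = rev, strand = "-")
        }
        if (!length(hits)) next
        h <- do.call(rbind, hits)
        if (nrow(h) > maxPlacements) next
        h$read_id <- names(reads)[i]
        h$width <- length(seq)
        h$n_placements <- nrow(h)
        rows[[length(rows) + 1L]] <- h
    }
    if (!length(rows))
        return(data.frame(contig = character(0), start = integer(0),
                          strand = character(0), read_id = character(0),
                          width = integer(0), n_placements = integer(0)))
    do.call(rbind, rows)
}

## Canonical sortable key for a placement set.
placement_key <- function(df) {
    sort(sprintf("%s:%s:%d:%s:%d", df$read_id, df$contig, df$start,
                 df$strand, df$width))
}

aln_to_df <- function(aln) {
    data.frame(contig = as.character(seqnames(aln)), start = start(aln),
               strand = as.character(strand(aln)),
               read_id = mcols(aln)$read_id, width = width(aln),
               n_placements = mcols(aln)$n_placements)
}

## Oracle 2: O(n^2) all-ordered-pairs Dicer scan.
oracle_pairs <- function(aln, sizeRange = c(15, 31), overhang = 2,
                         mode = "literal") {
    n <- length(aln)
    st <- start(aln); en <- end(aln); w <- width(aln)
    str <- as.character(strand(aln)); ctg <- as.character(seqnames(aln))
    out <- matrix(0L, sizeRange[2] - sizeRange[1] + 1L,
                  sizeRange[2] - sizeRange[1] + 1L,
                  dimnames = list(sizeRange[1]:sizeRange[2],
                                  sizeRange[1]:sizeRange[2]))
    paired <- logical(n)
    if (n >= 2) for (q in seq_len(n)) for (p in seq_len(n)) {
        if (q == p) next
        if (ctg[q] != ctg[p] || str[q] == str[p]) next
        if (w[q] < sizeRange[1] || w[q] > sizeRange[2]) next
        if (w[p] < sizeRange[1] || w[p] > sizeRange[2]) next
        v <- min(en[q], en[p]) - max(st[q], st[p]) + 1L
        if (v != w[q] - overhang) next
        if (mode == "canonical") {
            ok <- if (str[q] == "+") en[p] == en[q] - overhang
                  else st[p] == st[q] + overhang
            if (!ok) next
        }
        out[as.character(w[q]), as.character(w[p])] <-
            out[as.character(w[q]), as.character(w[p])] + 1L
        paired[q] <- TRUE; paired[p] <- TRUE
    }
    list(counts = out, paired_ids = unique(mcols(aln)$read_id[paired]))
}

## Oracle 3: per-base coverage scan locus caller (single contig).
oracle_loci <- function(aln, minDepth = 2, minLength = 40, contigLen) {
    depth <- integer(contigLen)
    for (i in seq_along(aln))
        depth[start(aln)[i]:end(aln)[i]] <-
            depth[start(aln)[i]:end(aln)[i]] + 1L
    above <- depth >= minDepth
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & runs$lengths > minLength
    if (!any(keep))
        return(data.frame(start = integer(0), end = integer(0),
                          n_reads = integer(0)))
    df <- data.frame(start = starts[keep], end = ends[keep])
    df$n_reads <- vapply(seq_len(nrow(df)), function(i)
        sum(start(aln) <= df$end[i] & end(aln) >= df$start[i]),
        integer(1))
    df
}

## Oracle 4: all-pairs interval intersection.
oracle_intersect <- function(A, B) {
    hitA <- vapply(seq_along(A), function(i)
        any(as.character(seqnames(B)) == as.character(seqnames(A))[i] &
            start(B) <= end(A)[i] & end(B) >= start(A)[i]),
        logical(1))
    hitB <- vapply(seq_along(B), function(i)
        any(as.character(seqnames(A)) == as.character(seqnames(B))[i] &
            start(A) <= end(B)[i] & end(A) >= start(B)[i]),
        logical(1))
    list(A_only = sum(!hitA), B_only = sum(!hitB), shared = sum(hitA),
         pct_A_not_in_B = if (length(A)) 100 * mean(!hitA) else NA_real_)
}

## 3-sigma binomial band check.
within_3sigma <- function(obs_frac, p, n) {
    abs(obs_frac - p) <= 3 * sqrt(p * (1 - p) / n)
}
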