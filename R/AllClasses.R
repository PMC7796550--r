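## Central S4 containers.  All genomic intervals in this package are
## Bioconductor-convention GRanges: 1-based, closed.  Conversion to/from
## 0-based half-open coordinates happens only at the BED/SAM boundary.

#' SimulationConfig: the stated world of the read simulator
#'
#' Holds every generative constant of the synthetic small RNA libraries:
#' Dicer duplex geometry (2-nt 3' overhangs, 18-23 nt products), piRNA
#' ping-pong geometry (10-nt 5'-5' overlap, 25-30 nt, 5'U primary /
#' position-10 A secondary biases), plant 24-nt Dicer products, and a
#' uniform degradation background whose weight differs between an
#' Argonaute-enriched ("enriched") and a total-RNA ("total") library
#' condition.
#'
#' @slot seed integer; master seed, all simulator output is a deterministic
#'   function of it.
#' @slot genomeLengths named numeric; bp per compartment. Compartments
#'   `nuclear`, `plastid`, `plant` and `trigger` are expected downstream.
#' @slot dicerSizeDist named numeric; probability over duplex lengths
#'   (names are lengths in nt); must sum to 1.
#' @slot overhang integer; 3' overhang left by Dicer (nt).
#' @slot duplexAsymmetry named numeric; probability over the partner-strand
#'   length offset delta (partner length = duplex length + delta). Offsets
#'   below `-overhang` would make a duplex undetectable by the overlap rule
#'   and are rejected.
#' @slot pingpongOverlap integer; 5'-5' overlap of ping-pong pairs (nt).
#' @slot primary5pBias numeric; probability that a primary piRNA starts
#'   with U (T in DNA space). Because a secondary piRNA's position-10 base
#'   is the Watson-Crick complement of the primary 5' base when the 5' ends
#'   overlap by exactly 10 nt, the same reference base realises both the 5'U
#'   and the 10A bias; `secondary10ABias` is honoured exactly when equal to
#'   `primary5pBias` (the default) and is retained as a separate field for
#'   reporting.
#' @slot secondary10ABias numeric; see above.
#' @slot piRNASizeRange integer(2); piRNA length bounds (nt).
#' @slot plantSRNASize integer; plant Dicer product length (nt).
#' @slot degradationSizeRange integer(2); degradation fragment lengths are
#'   uniform over this range (nt).
#' @slot degradationFraction numeric in [0,1]; fraction of a mixed library
#'   that is degradation background.
#' @slot depth integer; reads generated per signal class.
#' @slot condition `"enriched"` or `"total"`.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        seed = "integer",
        genomeLengths = "numeric",
        dicerSizeDist = "numeric",
        overhang = "integer",
        duplexAsymmetry = "numeric",
        pingpongOverlap = "integer",
        primary5pBias = "numeric",
        secondary10ABias = "numeric",
        piRNASizeRange = "integer",
        plantSRNASize = "integer",
        degradationSizeRange = "integer",
        degradationFraction = "numeric",
        depth = "integer",
        condition = "character"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (abs(sum(object@dicerSizeDist) - 1) > 1e-9)
        msg <- c(msg, "dicerSizeDist must sum to 1 (tolerance 1e-9)")
    if (any(object@dicerSizeDist < 0))
        msg <- c(msg, "dicerSizeDist must be non-negative")
    if (is.null(names(object@dicerSizeDist)) ||
        anyNA(suppressWarnings(as.integer(names(object@dicerSizeDist)))))
        msg <- c(msg, "dicerSizeDist must be named by read length")
    if (abs(sum(object@duplexAsymmetry) - 1) > 1e-9)
        msg <- c(msg, "duplexAsymmetry must sum to 1 (tolerance 1e-9)")
    offs <- suppressWarnings(as.integer(names(object@duplexAsymmetry)))
    if (anyNA(offs))
        msg <- c(msg, "duplexAsymmetry must be named by integer offsets")
    else if (any(offs < -object@overhang))
        msg <- c(msg, sprintf(
            "duplexAsymmetry offsets below -%d break duplex detectability",
            object@overhang))
    if (object@overhang < 0L) msg <- c(msg, "overhang must be >= 0")
    if (object@pingpongOverlap < 1L)
        msg <- c(msg, "pingpongOverlap must be >= 1")
    if (object@pingpongOverlap > min(object@piRNASizeRange))
        msg <- c(msg, "pingpongOverlap exceeds minimum piRNA length")
    if (object@primary5pBias < 0 || object@primary5pBias > 1 ||
        object@secondary10ABias < 0 || object@secondary10ABias > 1)
        msg <- c(msg, "piRNA biases must lie in [0,1]")
    if (object@degradationFraction < 0 || object@degradationFraction > 1)
        msg <- c(msg, "degradationFraction must lie in [0,1]")
    if (any(object@genomeLengths <= 0))
        msg <- c(msg, "all genome compartment lengths must be positive")
    if (is.null(names(object@genomeLengths)))
        msg <- c(msg, "genomeLengths must be named by compartment")
    if (object@depth < 0L) msg <- c(msg, "depth must be >= 0")
    if (!object@condition %in% c("enriched", "total"))
        msg <- c(msg, "condition must be 'enriched' or 'total'")
    if (diff(object@piRNASizeRange) < 0 ||
        diff(object@degradationSizeRange) < 0)
        msg <- c(msg, "size ranges must be increasing")
    if (length(msg)) msg else TRUE
})

#' GenomeIndex: k-mer seed index for the perfect-match aligner
#'
#' Every forward-strand genomic k-mer is retrievable with its occurrence
#' positions; reads are looked up on both strands by querying the read and
#' its reverse complement. Seeds are verified by full-length exact
#' comparison, so `k` affects speed only, never the placement set.
#'
#' @slot seqs DNAStringSet; the reference contigs.
#' @slot k integer; seed length.
#' @slot table environment; hash from k-mer string to an integer matrix
#'   with columns `contig` (index into `seqs`) and `pos` (1-based start).
#' @exportClass GenomeIndex
setClass("GenomeIndex",
    representation(seqs = "DNAStringSet", k = "integer",
                   table = "environment")
)

setValidity("GenomeIndex", function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (length(object@seqs) == 0L) return("empty reference")
    TRUE
})

#' PairMatrix: Dicer duplex overlap-pair counts
#'
#' Counts of opposite-strand alignment pairs in which the genomic overlap
#' equals the query read length minus the configured 3' overhang -- the
#' signature of RNase III (Dicer) cleavage. Indexed (query length, partner
#' length); asymmetric by construction because the criterion is relative to
#' the query length.
#'
#' @slot counts integer matrix, dimnames = read lengths.
#' @slot sizeRange integer(2).
#' @slot overhang integer.
#' @slot mode `"literal"` (overlap-length rule only) or `"canonical"`
#'   (additionally requires the partner 5' end to sit `overhang` nt inside
#'   the query 3' end -- the register of a true Dicer duplex).
#' @slot nAlignments integer; alignments considered.
#' @exportClass PairMatrix
setClass("PairMatrix",
    representation(counts = "matrix", sizeRange = "integer",
                   overhang = "integer", mode = "character",
                   nAlignments = "integer")
)

setValidity("PairMatrix", function(object) {
    if (any(object@counts < 0)) return("pair counts must be non-negative")
    if (!object@mode %in% c("literal", "canonical"))
        return("mode must be 'literal' or 'canonical'")
    TRUE
})

#' OverlapHistogram: 5'-5' opposite-strand overlap counts (ping-pong)
#'
#' For every (+,-) alignment pair on a contig the 5' ends may overlap by
#' o nt; piRNA ping-pong amplification over-represents o = 10. The z-score
#' at an offset is (count - mean of the other offsets) / sd of the other
#' offsets.
#'
#' @slot counts integer vector named by offset 1..maxOffset.
#' @slot zscores numeric vector, same names.
#' @exportClass OverlapHistogram
setClass("OverlapHistogram",
    representation(counts = "numeric", zscores = "numeric")
)

#' PositionFrequencyMatrix: positional base composition of reads
#'
#' Frequencies are computed on the read-sense sequence (for minus-strand
#' alignments, the reverse complement of the genomic slice), positions
#' 1-based from the 5' end. Reads shorter than a position contribute only
#' to the positions they cover; per-position denominators are tracked.
#'
#' @slot freq numeric matrix 4 x N, rows A,C,G,T; each column sums to 1
#'   over the reads covering it.
#' @slot baseCounts integer matrix 4 x N of raw counts.
#' @slot nReads integer.
#' @exportClass PositionFrequencyMatrix
setClass("PositionFrequencyMatrix",
    representation(freq = "matrix", baseCounts = "matrix",
                   nReads = "integer")
)

setValidity("PositionFrequencyMatrix", function(object) {
    cs <- colSums(object@freq)
    covered <- colSums(object@baseCounts) > 0
    if (any(abs(cs[covered] - 1) > 1e-9))
        return("covered-position frequencies must sum to 1 (tol 1e-9)")
    TRUE
})

#' SizeDistribution: read-length histogram
#'
#' @slot counts integer vector named by length (default 15..31 nt).
#' @slot total integer.
#' @exportClass SizeDistribution
setClass("SizeDistribution",
    representation(counts = "numeric", total = "integer")
)

setValidity("SizeDistribution", function(object) {
    if (sum(object@counts) != object@total)
        return("counts must sum to total")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
})

#' CoverageProfile: per-base, per-strand depth over one contig
#'
#' @slot contig character.
#' @slot plus,minus integer [S4Vectors::Rle] depth vectors, length = contig
#'   length.
#' @slot filters list recording the size-range / uniqueness filters applied.
#' @exportClass CoverageProfile
setClass("CoverageProfile",
    representation(contig = "character", plus = "Rle", minus = "Rle",
                   filters = "list")
)

setValidity("CoverageProfile", function(object) {
    if (length(object@plus) != length(object@minus))
        return("strand depth vectors must have equal length")
    if (min(object@plus) < -1e-9 || min(object@minus) < -1e-9)
        return("depths must be non-negative")  # fp tolerance for weights
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig (condition:", object@condition, ")\n")
    cat("  seed:", object@seed, " depth/class:", object@depth, "\n")
    cat("  compartments:",
        paste(sprintf("%s=%d", names(object@genomeLengths),
                      as.integer(object@genomeLengths)), collapse = ", "),
        "\n")
    cat("  Dicer sizes:", paste(names(object@dicerSizeDist), collapse = ","),
        " overhang:", object@overhang, "nt\n")
    cat("  ping-pong overlap:", object@pingpongOverlap,
        "nt  5'U bias:", object@primary5pBias,
        " 10A bias:", object@secondary10ABias, "\n")
    cat("  degradation fraction:", object@degradationFraction, "\n")
})

setMethod("show", "GenomeIndex", function(object) {
    cat("GenomeIndex:", length(object@seqs), "contig(s),",
        sum(Biostrings::width(object@seqs)), "bp, k =", object@k, "\n")
})

setMethod("show", "PairMatrix", function(object) {
    cat("PairMatrix (", object@mode, " mode, overhang ", object@overhang,
        " nt): ", sum(object@counts), " pairs from ", object@nAlignments,
        " alignments\n", sep = "")
    nz <- which(object@counts > 0, arr.ind = TRUE)
    if (nrow(nz)) {
        top <- head(order(object@counts[nz], decreasing = TRUE), 5L)
        for (i in top)
            cat(sprintf("  (q=%s, t=%s): %d\n",
                        rownames(object@counts)[nz[i, 1]],
                        colnames(object@counts)[nz[i, 2]],
                        object@counts[nz[i, , drop = FALSE]]))
    }
})

setMethod("show", "OverlapHistogram", function(object) {
    peak <- names(which.max(object@counts))
    cat("OverlapHistogram: offsets 1..", length(object@counts),
        "; peak at ", peak, " (z = ",
        round(object@zscores[peak], 2), ")\n", sep = "")
})

setMethod("show", "PositionFrequencyMatrix", function(object) {
    cat("PositionFrequencyMatrix:", ncol(object@freq), "positions,",
        object@nReads, "reads\n")
    cat("  pos1:", paste(sprintf("%s=%.2f", rownames(object@freq),
                                 object@freq[, 1]), collapse = " "), "\n")
})

setMethod("show", "SizeDistribution", function(object) {
    cat("SizeDistribution:", object@total, "reads, lengths",
        names(object@counts)[1], "-",
        names(object@counts)[length(object@counts)], "nt; mode",
        names(which.max(object@counts)), "nt\n")
})

setMethod("show", "CoverageProfile", function(object) {
    cat("CoverageProfile for", object@contig, "(",
        length(object@plus), "bp )\n")
    cat("  covered + :", sum(object@plus > 0), "bp;  - :",
        sum(object@minus > 0), "bp\n")
    if (length(object@filters))
        cat("  filters:", paste(names(object@filters), "=",
            vapply(object@filters, function(x) paste(x, collapse = ":"),
                   character(1)), collapse = "; "), "\n")
})
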