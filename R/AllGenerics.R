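## Generics and accessors.  `counts` reuses the BiocGenerics generic.

#' @importFrom BiocGenerics counts
#' @export
BiocGenerics::counts

#' Extract the count table of a result object
#'
#' @param object a [PairMatrix-class], [OverlapHistogram-class] or
#'   [SizeDistribution-class].
#' @param ... ignored.
#' @return the integer count matrix / vector.
#' @aliases counts,PairMatrix-method counts,OverlapHistogram-method
#'   counts,SizeDistribution-method
#' @rdname counts-methods
#' @export
setMethod("counts", "PairMatrix", function(object, ...) object@counts)

#' @rdname counts-methods
#' @export
setMethod("counts", "OverlapHistogram", function(object, ...) object@counts)

#' @rdname counts-methods
#' @export
setMethod("counts", "SizeDistribution", function(object, ...) object@counts)

#' Per-offset z-scores of an overlap histogram
#'
#' @param object an [OverlapHistogram-class].
#' @return named numeric vector, z-score per offset (count minus the mean of
#'   the other offsets, over their standard deviation).
#' @export
setGeneric("zscores", function(object) standardGeneric("zscores"))

#' @rdname zscores
#' @export
setMethod("zscores", "OverlapHistogram", function(object) object@zscores)

#' Positional base frequencies
#'
#' @param object a [PositionFrequencyMatrix-class].
#' @return 4 x N numeric matrix (rows A, C, G, T), columns summing to 1
#'   over the reads that cover them.
#' @export
setGeneric("baseFrequencies",
           function(object) standardGeneric("baseFrequencies"))

#' @rdname baseFrequencies
#' @export
setMethod("baseFrequencies", "PositionFrequencyMatrix",
          function(object) object@freq)

#' Length fractions of a size distribution
#'
#' @param object a [SizeDistribution-class].
#' @return named numeric vector of per-length fractions (sums to 1 when the
#'   distribution is non-empty; all-zero otherwise).
#' @export
setGeneric("asFractions", function(object) standardGeneric("asFractions"))

#' @rdname asFractions
#' @export
setMethod("asFractions", "SizeDistribution", function(object) {
    if (object@total == 0L) return(object@counts * 0)
    object@counts / object@total
})

#' Strand depth vectors of a coverage profile
#'
#' @param object a [CoverageProfile-class].
#' @param strand `"+"` or `"-"`.
#' @return integer [S4Vectors::Rle] of per-base depth.
#' @export
setGeneric("strandDepth",
           function(object, strand = "+") standardGeneric("strandDepth"))

#' @rdname strandDepth
#' @export
setMethod("strandDepth", "CoverageProfile", function(object, strand = "+") {
    strand <- match.arg(strand, c("+", "-"))
    if (strand == "+") object@plus else object@minus
})
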