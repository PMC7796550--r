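## Generative simulator for small RNA libraries with per-read ground truth.
##
## The stated world: Dicer dices double-stranded substrates into short
## duplexes (18-23 nt) whose strands carry 2-nt 3' overhangs; piRNA
## ping-pong amplification yields 25-30 nt opposite-strand pairs whose 5'
## ends overlap by exactly 10 nt, with a 5'U bias on primary reads and a
## position-10 A bias on secondaries; plant Dicer emits 24-nt products from
## discrete loci; degradation produces short (15-19 nt) fragments placed
## uniformly.  An "enriched" library condition (Argonaute-bound RNA after
## anion-exchange chromatography) carries a low degradation fraction, a
## "total" RNA condition a high one.

#' Construct a simulation configuration
#'
#' All defaults encode the generative constants of the modelled libraries;
#' see [SimulationConfig-class] for the meaning of each field.
#'
#' @param seed integer master seed.
#' @param condition `"enriched"` or `"total"`; selects the default
#'   degradation fraction (0.1 vs 0.8). The total condition models
#'   unfractionated RNA and must not have less background than the
#'   enriched one.
#' @param genomeLengths named numeric, bp per compartment.
#' @param dicerSizeDist named probability vector over Dicer product lengths.
#' @param overhang Dicer 3' overhang in nt.
#' @param duplexAsymmetry named probability vector over the partner-length
#'   offset; the default concentrates on offsets 0 and +/-1, +/-2 nt,
#'   matching duplexes that are symmetric or offset by one or two bases.
#' @param pingpongOverlap piRNA 5'-5' overlap in nt.
#' @param primary5pBias,secondary10ABias piRNA nucleotide biases in [0,1].
#' @param piRNASizeRange integer(2), piRNA length bounds.
#' @param plantSRNASize plant Dicer product length in nt.
#' @param degradationSizeRange integer(2), degradation fragment lengths
#'   (uniform).
#' @param degradationFraction override of the per-condition default.
#' @param depth reads generated per signal class.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, condition = "enriched")
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
        condition = c("enriched", "total"),
        genomeLengths = c(nuclear = 50000, plastid = 20000,
                          plant = 50000, trigger = 350),
        dicerSizeDist = c(`18` = 0.05, `19` = 0.15, `20` = 0.25,
                          `21` = 0.35, `22` = 0.15, `23` = 0.05),
        overhang = 2L,
        duplexAsymmetry = c(`-2` = 0.1, `-1` = 0.15, `0` = 0.5,
                            `1` = 0.15, `2` = 0.1),
        pingpongOverlap = 10L,
        primary5pBias = 0.8,
        secondary10ABias = primary5pBias,
        piRNASizeRange = c(25L, 30L),
        plantSRNASize = 24L,
        degradationSizeRange = c(15L, 19L),
        degradationFraction = NULL,
        depth = 2000L) {
    condition <- match.arg(condition)
    if (is.null(degradationFraction))
        degradationFraction <- if (condition == "enriched") 0.1 else 0.8
    new("SimulationConfig",
        seed = as.integer(seed),
        genomeLengths = genomeLengths,
        dicerSizeDist = dicerSizeDist,
        overhang = as.integer(overhang),
        duplexAsymmetry = duplexAsymmetry,
        pingpongOverlap = as.integer(pingpongOverlap),
        primary5pBias = primary5pBias,
        secondary10ABias = secondary10ABias,
        piRNASizeRange = as.integer(piRNASizeRange),
        plantSRNASize = as.integer(plantSRNASize),
        degradationSizeRange = as.integer(degradationSizeRange),
        degradationFraction = degradationFraction,
        depth = as.integer(depth),
        condition = condition)
}

.random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate reference sequences and mock annotations
#'
#' Emits one random contig per configured compartment (uniform base
#' composition) and BED-style annotations for mock miRNA / tRNA / rRNA /
#' endogenous small RNA loci on the nuclear contig.  Stands in for the
#' public mite, bean and plastid assemblies a real analysis would load.
#'
#' @param config a [SimulationConfig-class].
#' @param nAnnotations loci generated per annotation class.
#' @param annotationWidth width of each mock annotation interval (bp).
#' @param seed seed; defaults to `config@seed`. `NULL` uses the current RNG
#'   stream.
#' @return list with elements `genome` (named [Biostrings::DNAStringSet])
#'   and `annotations` ([GenomicRanges::GRanges] with a `class` metadata
#'   column).
#' @examples
#' refs <- makeReferences(simulationConfig(seed = 1))
#' refs$genome
#' @export
makeReferences <- function(config, nAnnotations = 5L, annotationWidth = 80L,
                           seed = config@seed) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    gl <- config@genomeLengths
    run <- function() {
        genome <- DNAStringSet(vapply(gl, .random_dna, character(1)))
        names(genome) <- names(gl)
        anno_contig <- if ("nuclear" %in% names(gl)) "nuclear" else
            names(gl)[which.max(gl)]
        L <- gl[[anno_contig]]
        classes <- c("miRNA", "tRNA", "rRNA", "endo_sRNA")
        w <- min(annotationWidth, L)
        starts <- sample.int(max(1L, L - w + 1L),
                             nAnnotations * length(classes), replace = TRUE)
        anno <- GRanges(anno_contig,
                        IRanges(starts, width = w),
                        strand = sample(c("+", "-"),
                                        length(starts), replace = TRUE),
                        class = rep(classes, each = nAnnotations))
        seqlengths(anno) <- setNames(as.integer(L), anno_contig)
        list(genome = genome, annotations = anno)
    }
    if (is.null(seed)) run() else with_seed(seed, run())
}

## Extract read-sense sequences for intervals on one contig.
.slice_seqs <- function(contigseq, start, end, strand) {
    v <- Biostrings::Views(contigseq, start = start, end = end)
    out <- as(v, "DNAStringSet")
    neg <- strand == "-"
    if (any(neg)) out[neg] <- reverseComplement(out[neg])
    out
}

.truth_df <- function(read_id, class, contig, start, end, strand,
                      partner = NA_character_) {
    data.frame(read_id = read_id, class = class, contig = contig,
               start = as.integer(start), end = as.integer(end),
               strand = strand, partner = partner,
               stringsAsFactors = FALSE)
}

.region_bounds <- function(genome, contig, region) {
    L <- length(genome[[contig]])
    if (is.null(region)) c(1L, L)
    else {
        stopifnot(region[1] >= 1L, region[2] <= L, region[1] <= region[2])
        as.integer(region)
    }
}

#' Simulate Dicer-cleaved duplex reads
#'
#' Each duplex draws a sense length q from `dicerSizeDist` and a partner
#' length `q + delta` (delta from `duplexAsymmetry`), placed so that the
#' antisense 5' end lies `overhang` nt inside the sense 3' end -- the
#' register of a 2-nt 3' overhang duplex.  For symmetric duplexes
#' (delta = 0) both 3' ends then overhang the opposite 5' end by exactly
#' `overhang` nt, and the genomic overlap between partners equals
#' q - overhang.
#'
#' @param genome named DNAStringSet.
#' @param contig contig name to dice.
#' @param config a [SimulationConfig-class].
#' @param n number of duplexes (2n reads).
#' @param region optional integer(2), 1-based closed sub-interval.
#' @param idPrefix prefix for read identifiers.
#' @param seed as in [makeReferences()].
#' @return list(reads = DNAStringSet, truth = data.frame). Truth rows carry
#'   1-based closed coordinates and the partner read id.
#' @export
simulateDicerReads <- function(genome, contig, config, n,
                               region = NULL, idPrefix = "dicer",
                               seed = config@seed) {
    rb <- .region_bounds(genome, contig, region)
    sizes <- as.integer(names(config@dicerSizeDist))
    deltas <- as.integer(names(config@duplexAsymmetry))
    maxq <- max(sizes) + max(deltas)
    if (rb[2] - rb[1] + 1L <= maxq + config@overhang)
        stop("source interval must be longer than the maximum duplex length")
    run <- function() {
        q <- sizes[sample.int(length(sizes), n, replace = TRUE,
                              prob = config@dicerSizeDist)]
        delta <- deltas[sample.int(length(deltas), n, replace = TRUE,
                                   prob = config@duplexAsymmetry)]
        t <- q + delta
        lo <- rb[1] + pmax(0L, config@overhang + delta)
        hi <- rb[2] - q + 1L
        if (any(hi < lo)) stop("region too short for requested duplexes")
        s <- lo + floor(runif(n) * (hi - lo + 1L))
        me <- s + q - 1L - config@overhang   # antisense 5' end
        ms <- me - t + 1L
        sense_id <- sprintf("%s_%05d_s", idPrefix, seq_len(n))
        anti_id <- sprintf("%s_%05d_a", idPrefix, seq_len(n))
        reads <- c(.slice_seqs(genome[[contig]], s, s + q - 1L,
                               rep("+", n)),
                   .slice_seqs(genome[[contig]], ms, me, rep("-", n)))
        names(reads) <- c(sense_id, anti_id)
        truth <- rbind(
            .truth_df(sense_id, "dicer_duplex", contig, s, s + q - 1L,
                      "+", anti_id),
            .truth_df(anti_id, "dicer_duplex", contig, ms, me, "-",
                      sense_id))
        list(reads = reads, truth = truth)
    }
    if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate piRNA ping-pong read pairs
#'
#' Primary reads sit on the plus strand; each secondary read sits on the
#' minus strand with its 5' end overlapping the primary's 5' end by exactly
#' `pingpongOverlap` nt.  The 5'U bias is realised by drawing the primary 5'
#' position from reference T positions with probability `primary5pBias`
#' (from non-T positions otherwise), so every read still matches the
#' reference exactly.  Because the secondary's position-`pingpongOverlap`
#' base is the complement of the primary's 5' base, the position-10 A bias
#' follows from the same choice.
#'
#' @inheritParams simulateDicerReads
#' @param n number of ping-pong pairs (2n reads).
#' @return list(reads, truth) as in [simulateDicerReads()]; classes are
#'   `pingpong_primary` / `pingpong_secondary`.
#' @export
simulatePingPongReads <- function(genome, contig, config, n,
                                  region = NULL, idPrefix = "pp",
                                  seed = config@seed) {
    ov <- config@pingpongOverlap
    szr <- config@piRNASizeRange
    if (ov > szr[1])
        stop("pingpongOverlap exceeds the minimum piRNA length")
    rb <- .region_bounds(genome, contig, region)
    Lmax <- szr[2]
    lo <- rb[1] + Lmax - ov     # secondary start stays in region
    hi <- rb[2] - Lmax + 1L     # primary end stays in region
    if (hi < lo) stop("source interval too short for piRNA pairs")
    basechars <- strsplit(as.character(subseq(genome[[contig]], lo, hi)),
                          "", fixed = TRUE)[[1]]
    tpos <- lo - 1L + which(basechars == "T")
    npos <- lo - 1L + which(basechars != "T")
    if (!length(tpos) || !length(npos))
        stop("region lacks base diversity for the 5' bias model")
    run <- function() {
        useT <- runif(n) < config@primary5pBias
        p <- integer(n)
        p[useT] <- tpos[sample.int(length(tpos), sum(useT), replace = TRUE)]
        p[!useT] <- npos[sample.int(length(npos), sum(!useT),
                                    replace = TRUE)]
        piL <- szr[1]:szr[2]
        L1 <- piL[sample.int(length(piL), n, replace = TRUE)]
        L2 <- piL[sample.int(length(piL), n, replace = TRUE)]
        pri_id <- sprintf("%s_%05d_p", idPrefix, seq_len(n))
        sec_id <- sprintf("%s_%05d_q", idPrefix, seq_len(n))
        sec_end <- p + ov - 1L
        sec_start <- sec_end - L2 + 1L
        reads <- c(.slice_seqs(genome[[contig]], p, p + L1 - 1L,
                               rep("+", n)),
                   .slice_seqs(genome[[contig]], sec_start, sec_end,
                               rep("-", n)))
        names(reads) <- c(pri_id, sec_id)
        truth <- rbind(
            .truth_df(pri_id, "pingpong_primary", contig, p, p + L1 - 1L,
                      "+", sec_id),
            .truth_df(sec_id, "pingpong_secondary", contig, sec_start,
                      sec_end, "-", pri_id))
        list(reads = reads, truth = truth)
    }
    if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate uniform degradation fragments
#'
#' Fragment starts are uniform over the source interval; lengths are
#' uniform over `degradationSizeRange` (default 15-19 nt, the short sizes
#' typical of degradation); strand is the source sense strand unless
#' `bothStrands`.
#'
#' @inheritParams simulateDicerReads
#' @param n number of fragments.
#' @param bothStrands if TRUE fragments fall on either strand with equal
#'   probability.
#' @export
simulateDegradation <- function(genome, contig, config, n,
                                region = NULL, bothStrands = FALSE,
                                idPrefix = "deg", seed = config@seed) {
    rb <- .region_bounds(genome, contig, region)
    szr <- config@degradationSizeRange
    if (rb[2] - rb[1] + 1L < szr[2])
        stop("source interval shorter than the maximum fragment length")
    run <- function() {
        dlen <- szr[1]:szr[2]
        len <- dlen[sample.int(length(dlen), n, replace = TRUE)]
        s <- rb[1] + floor(runif(n) * (rb[2] - len - rb[1] + 2L))
        str <- if (bothStrands) sample(c("+", "-"), n, replace = TRUE)
               else rep("+", n)
        ids <- sprintf("%s_%05d", idPrefix, seq_len(n))
        reads <- .slice_seqs(genome[[contig]], s, s + len - 1L, str)
        names(reads) <- ids
        truth <- .truth_df(ids, "degradation", contig, s, s + len - 1L, str)
        list(reads = reads, truth = truth)
    }
    if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate plant 24-nt small RNAs from discrete loci
#'
#' Emulates plant heterochromatic Dicer products: a set of loci is chosen
#' on the plant compartment and reads of length `plantSRNASize` are placed
#' uniformly within each locus on both strands.
#'
#' @inheritParams simulateDicerReads
#' @param n total reads.
#' @param nLoci number of source loci.
#' @param locusWidth width of each source locus (bp).
#' @return list(reads, truth, loci) where `loci` is a GRanges of the true
#'   source intervals.
#' @export
simulatePlantReads <- function(genome, contig = "plant", config, n,
                               nLoci = 10L, locusWidth = 150L,
                               idPrefix = "plant", seed = config@seed) {
    rb <- .region_bounds(genome, contig, NULL)
    w <- config@plantSRNASize
    if (locusWidth < w) stop("locusWidth must be >= plantSRNASize")
    run <- function() {
        ls <- sort(sample.int(rb[2] - locusWidth + 1L, nLoci))
        locus <- sample.int(nLoci, n, replace = TRUE)
        s <- ls[locus] + floor(runif(n) * (locusWidth - w + 1L))
        str <- sample(c("+", "-"), n, replace = TRUE)
        ids <- sprintf("%s_%05d", idPrefix, seq_len(n))
        reads <- .slice_seqs(genome[[contig]], s, s + w - 1L, str)
        names(reads) <- ids
        truth <- .truth_df(ids, "plant_sRNA", contig, s, s + w - 1L, str)
        loci <- GRanges(contig, IRanges(ls, width = locusWidth))
        list(reads = reads, truth = truth, loci = loci)
    }
    if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a complete mixed small RNA library
#'
#' Combines Dicer duplexes diced from the `trigger` compartment, ping-pong
#' piRNA pairs from the `nuclear` compartment, plant 24-nt locus reads, and
#' a degradation background spread over compartments in proportion to their
#' lengths.  Signal classes each contribute `config@depth` reads; the
#' degradation read count is chosen so the configured
#' `degradationFraction` of the final library is background.
#'
#' @param config a [SimulationConfig-class].
#' @param references optional precomputed [makeReferences()] output; pass
#'   the same object to both conditions to dice the same substrates.
#' @param classes signal classes to include.
#' @return list with `reads` (DNAStringSet), `truth` (data.frame),
#'   `references`, and `config`.
#' @examples
#' lib <- simulateLibrary(simulationConfig(seed = 1, depth = 200L))
#' table(lib$truth$class)
#' @export
simulateLibrary <- function(config, references = NULL,
        classes = c("dicer_duplex", "pingpong", "plant_sRNA")) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (is.null(references)) references <- makeReferences(config)
    genome <- references$genome
    reads <- DNAStringSet()
    truth <- NULL
    seed <- config@seed
    n_signal <- 0L
    if ("dicer_duplex" %in% classes && config@depth > 0L) {
        d <- simulateDicerReads(genome, "trigger", config,
                                n = max(1L, config@depth %/% 2L),
                                seed = seed + 11L)
        reads <- c(reads, d$reads); truth <- rbind(truth, d$truth)
        n_signal <- n_signal + length(d$reads)
    }
    if ("pingpong" %in% classes && config@depth > 0L) {
        p <- simulatePingPongReads(genome, "nuclear", config,
                                   n = max(1L, config@depth %/% 2L),
                                   seed = seed + 12L)
        reads <- c(reads, p$reads); truth <- rbind(truth, p$truth)
        n_signal <- n_signal + length(p$reads)
    }
    if ("plant_sRNA" %in% classes && config@depth > 0L) {
        pl <- simulatePlantReads(genome, "plant", config, n = config@depth,
                                 seed = seed + 13L)
        reads <- c(reads, pl$reads); truth <- rbind(truth, pl$truth)
        n_signal <- n_signal + length(pl$reads)
    }
    f <- config@degradationFraction
    if (f > 0 && n_signal > 0L) {
        n_deg <- round(f / (1 - f) * n_signal)
        comps <- intersect(c("nuclear", "plastid", "trigger"), names(genome))
        wts <- config@genomeLengths[comps] / sum(config@genomeLengths[comps])
        per <- with_seed(seed + 14L,
                         as.vector(stats::rmultinom(1, n_deg, wts)))
        for (i in seq_along(comps)) {
            if (per[i] == 0L) next
            dg <- simulateDegradation(genome, comps[i], config, per[i],
                                      idPrefix = paste0("deg_", comps[i]),
                                      seed = seed + 20L + i)
            reads <- c(reads, dg$reads); truth <- rbind(truth, dg$truth)
        }
    }
    list(reads = reads, truth = truth, references = references,
         config = config)
}
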