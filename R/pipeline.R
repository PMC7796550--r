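## End-to-end orchestration: trim -> subsample -> map -> signature
## statistics, from one declarative config, with a machine-readable run
## report.  Stage outputs are cached on disk keyed by a hash of their
## parameters (and their upstream stage's hash), so partial reruns reuse
## earlier work.

.stage_cached <- function(cachedir, name, key, fun) {
    h <- param_hash(key)
    path <- file.path(cachedir, sprintf("%s-%s.rds", name, h))
    if (file.exists(path))
        return(list(value = readRDS(path), hash = h, cached = TRUE))
    value <- fun()
    saveRDS(value, path)
    list(value = value, hash = h, cached = FALSE)
}

#' Run the full small RNA signature pipeline
#'
#' Input is either a simulated library (`config$simulate`) or files
#' (`config$input$fastq` + `config$input$reference`, optionally
#' `config$input$annotations` as a BED file whose name field is the class).
#' Stages: adapter trimming (optional), subsampling (optional),
#' perfect-match mapping, then the Dicer pair matrix and read fraction,
#' ping-pong overlap histogram, strand fractions, locus calling, size
#' distribution, dual-strand coverage, and annotation classification.
#'
#' @param config nested list (or path to a JSON file): fields `seed`,
#'   `outdir`, `input` or `simulate`, and optional parameter blocks
#'   `trim` (`adapter`, `minOverlap`, `minLen`, `maxLen`), `subsample`
#'   (`n`), `map` (`k`, `maxPlacements`), `dicer` (`overhang`, `mode`,
#'   `sizeRange`), `pingpong` (`maxOffset`), `loci` (`minDepth`,
#'   `minLength`), `coverage` (`contig`), `sirna` (`lo`, `hi`). Defaults
#'   mirror the standard analysis: overhang 2, depth >= 2, length > 40,
#'   placement cap 200, sizes 15-31, siRNA sizes 19-23.
#' @return the run report (nested list), invisibly written as
#'   `report.json` in `outdir` together with the verbatim config.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config$outdir)) stop("config$outdir is required")
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    cachedir <- file.path(outdir, "cache")
    dir.create(cachedir, showWarnings = FALSE)
    jsonlite::write_json(config, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    report <- list(seed = seed, stages = list(), statistics = list())

    ## ---- input ----------------------------------------------------------
    if (isTRUE(config$simulate) || is.list(config$simulate)) {
        simargs <- if (is.list(config$simulate)) config$simulate else list()
        simargs$seed <- seed
        sc <- do.call(simulationConfig, simargs)
        st <- .stage_cached(cachedir, "simulate", simargs,
                            function() simulateLibrary(sc))
        lib <- st$value
        reads <- lib$reads
        genome <- lib$references$genome
        annotations <- lib$references$annotations
        report$stages$input <- list(kind = "simulate",
            n_reads = length(reads), cached = st$cached,
            condition = sc@condition,
            degradation_fraction = sc@degradationFraction)
        upstream <- st$hash
    } else {
        inp <- config$input
        if (is.null(inp$fastq) || is.null(inp$reference))
            stop("config$input must name 'fastq' and 'reference' files")
        for (p in unlist(inp))
            if (!file.exists(p)) stop("input file not found: ", p)
        reads <- readLibrary(inp$fastq)
        genome <- readDNAStringSet(inp$reference)
        names(genome) <- sub("\\s.*", "", names(genome))
        annotations <- NULL
        if (!is.null(inp$annotations)) {
            annotations <- rtracklayer::import(inp$annotations,
                                               format = "BED")
            S4Vectors::mcols(annotations)$class <-
                as.character(S4Vectors::mcols(annotations)$name)
        }
        report$stages$input <- list(kind = "files", fastq = inp$fastq,
            reference = inp$reference, n_reads = length(reads))
        upstream <- param_hash(inp)
    }

    ## ---- trim -----------------------------------------------------------
    if (!is.null(config$trim)) {
        tp <- config$trim
        st <- .stage_cached(cachedir, "trim", list(tp, upstream),
            function() trimAdapter(reads, adapter = tp$adapter,
                minOverlap = tp$minOverlap %||% 8L,
                minLen = tp$minLen %||% 15L,
                maxLen = tp$maxLen %||% 31L,
                allowUntrimmed = isTRUE(tp$allowUntrimmed)))
        reads <- st$value
        report$stages$trim <- c(tp, list(n_kept = length(reads),
                                         cached = st$cached))
        upstream <- st$hash
    }

    ## ---- subsample ------------------------------------------------------
    if (!is.null(config$subsample)) {
        n <- as.integer(config$subsample$n %||% config$subsample)
        st <- .stage_cached(cachedir, "subsample",
                            list(n, seed, upstream),
            function() subsampleReads(reads, n, seed = seed))
        reads <- st$value
        report$stages$subsample <- list(n = n, seed = seed,
                                        cached = st$cached)
        upstream <- st$hash
    }

    ## ---- map ------------------------------------------------------------
    mp <- config$map %||% list()
    st <- .stage_cached(cachedir, "map", list(mp, upstream), function() {
        idx <- buildIndex(genome, k = mp$k %||% 12L)
        mapPerfect(reads, idx,
                   maxPlacements = mp$maxPlacements %||% 200L)
    })
    aln <- st$value
    report$stages$map <- list(k = mp$k %||% 12L,
        maxPlacements = mp$maxPlacements %||% 200L,
        n_alignments = length(aln),
        n_mapped_reads = length(unique(S4Vectors::mcols(aln)$read_id)),
        cached = st$cached)

    ## ---- statistics -----------------------------------------------------
    dp <- config$dicer %||% list()
    sizeRange <- as.integer(dp$sizeRange %||% c(15L, 31L))
    overhang <- as.integer(dp$overhang %||% 2L)
    pm <- pairMatrix(aln, sizeRange = sizeRange, overhang = overhang,
                     mode = dp$mode %||% "literal")
    frac <- dicerReadFraction(aln, sizeRange = sizeRange,
                              overhang = overhang,
                              mode = dp$mode %||% "literal")
    writePairMatrix(pm, file.path(outdir, "pair_matrix.tsv"))
    sr <- config$sirna %||% list()
    report$statistics$dicer <- list(overhang = overhang,
        n_pairs = sum(counts(pm)), dicer_read_fraction = frac,
        sirna_size_fraction = sirnaSizeFraction(aln,
            lo = sr$lo %||% 19L, hi = sr$hi %||% 23L))

    pp <- config$pingpong %||% list()
    oh <- fivePrimeOverlapHist(aln, maxOffset = pp$maxOffset %||% 30L)
    peak <- as.integer(names(which.max(counts(oh))))
    report$statistics$pingpong <- list(
        peak_offset = if (sum(counts(oh))) peak else NA_integer_,
        z_at_10 = unname(zscores(oh)["10"]),
        counts = as.list(counts(oh)))

    sf <- strandFraction(aln)
    report$statistics$strand <- sf[c("plus", "minus", "n")]

    lp <- config$loci %||% list()
    loci <- callLoci(aln, minDepth = lp$minDepth %||% 2L,
                     minLength = lp$minLength %||% 40L,
                     mergeDistance = lp$mergeDistance %||% 0L)
    if (length(loci)) writeBed(loci, file.path(outdir, "loci.bed"))
    report$statistics$loci <- list(n_loci = length(loci),
        min_depth = lp$minDepth %||% 2L,
        min_length = lp$minLength %||% 40L)

    sd_ <- sizeDistribution(aln, sizeRange = sizeRange)
    report$statistics$size_distribution <- as.list(counts(sd_))

    cv <- config$coverage %||% list()
    ctg <- cv$contig %||% names(genome)[1]
    prof <- buildCoverage(aln, ctg,
                          contigLength = length(genome[[ctg]]))
    report$statistics$coverage <- c(list(contig = ctg),
                                    dualStrandFraction(prof))

    if (!is.null(annotations)) {
        ar <- annotateReads(aln, annotations)
        report$statistics$classes <- as.list(ar$fractions)
    }

    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
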