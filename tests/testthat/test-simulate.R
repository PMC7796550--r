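test_that("reference generation is deterministic, bounded, and sized", {
    cfg <- simulationConfig(seed = 1)
    r1 <- makeReferences(cfg)
    r2 <- makeReferences(cfg)
    f1 <- tempfile(); f2 <- tempfile()
    writeXStringSet(r1$genome, f1); writeXStringSet(r2$genome, f2)
    expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
    expect_identical(length(r1$genome[["trigger"]]), 350L)
    anno <- r1$annotations
    L <- seqlengths(anno)[as.character(seqnames(anno))]
    expect_true(all(start(anno) >= 1L & end(anno) <= L))
    expect_setequal(unique(mcols(anno)$class),
                    c("miRNA", "tRNA", "rRNA", "endo_sRNA"))
    expect_error(simulationConfig(genomeLengths = c(nuclear = 0)),
                 "positive")
})

test_that("dicer duplex geometry: 2-nt 3' overhangs in both registers", {
    cfg <- simulationConfig(seed = 3, genomeLengths = c(trigger = 400),
        dicerSizeDist = c(`21` = 1),
        duplexAsymmetry = c(`0` = 1))
    sim <- simulateDicerReads(makeReferences(cfg)$genome, "trigger",
                              cfg, n = 50)
    tr <- sim$truth
    sense <- tr[tr$strand == "+", ]
    anti <- tr[match(sense$partner, tr$read_id), ]
    # partner occupies [query_start - 2, query_end - 2]; overlap 19 = 21 - 2
    expect_true(all(anti$start == sense$start - 2L))
    expect_true(all(anti$end == sense$end - 2L))
    ovl <- pmin(sense$end, anti$end) - pmax(sense$start, anti$start) + 1L
    expect_true(all(ovl == 21L - 2L))
    # point-mass distribution -> all reads are 21-mers
    expect_true(all(width(sim$reads) == 21L))
})

test_that("duplex sizes recover the configured distribution (3-sigma)", {
    cfg <- simulationConfig(seed = 5,
        genomeLengths = c(trigger = 2000),
        dicerSizeDist = setNames(rep(0.2, 5), 19:23),
        duplexAsymmetry = c(`0` = 1))
    sim <- simulateDicerReads(makeReferences(cfg)$genome, "trigger",
                              cfg, n = 5000)
    sense <- sim$truth[sim$truth$strand == "+", ]
    lens <- sense$end - sense$start + 1L
    for (L in 19:23)
        expect_true(within_3sigma(mean(lens == L), 0.2, length(lens)))
})

test_that("every simulated read matches the reference over its interval", {
    cfg <- simulationConfig(seed = 7, depth = 300L)
    lib <- simulateLibrary(cfg)
    genome <- lib$references$genome
    for (i in seq_len(nrow(lib$truth))) {
        tr <- lib$truth[i, ]
        ref <- subseq(genome[[tr$contig]], tr$start, tr$end)
        if (tr$strand == "-") ref <- reverseComplement(ref)
        expect_identical(as.character(lib$reads[[tr$read_id]]),
                         as.character(ref))
    }
})

test_that("ping-pong pairs have exact 10-nt 5' overlaps and biases", {
    cfg <- simulationConfig(seed = 11, primary5pBias = 1.0,
                            genomeLengths = c(nuclear = 5000))
    sim <- simulatePingPongReads(makeReferences(cfg)$genome, "nuclear",
                                 cfg, n = 500)
    tr <- sim$truth
    pri <- tr[tr$class == "pingpong_primary", ]
    sec <- tr[match(pri$partner, tr$read_id), ]
    # secondary minus-strand 5' end sits at primary 5' + overlap - 1
    expect_true(all(sec$end == pri$start + 10L - 1L))
    # bias 1.0 -> every primary starts with T
    firsts <- substr(as.character(sim$reads[pri$read_id]), 1, 1)
    expect_true(all(firsts == "T"))
    # and every secondary carries A at position 10 (complement geometry)
    tenth <- substr(as.character(sim$reads[sec$read_id]), 10, 10)
    expect_true(all(tenth == "A"))
    expect_true(all(width(sim$reads) >= 25L & width(sim$reads) <= 30L))
})

test_that("configured 0.8 piRNA biases are recovered within 3 sigma", {
    cfg <- simulationConfig(seed = 13, primary5pBias = 0.8,
                            genomeLengths = c(nuclear = 20000))
    sim <- simulatePingPongReads(makeReferences(cfg)$genome, "nuclear",
                                 cfg, n = 2000)
    tr <- sim$truth
    pri <- tr$read_id[tr$class == "pingpong_primary"]
    sec <- tr$read_id[tr$class == "pingpong_secondary"]
    fT <- mean(substr(as.character(sim$reads[pri]), 1, 1) == "T")
    fA <- mean(substr(as.character(sim$reads[sec]), 10, 10) == "A")
    expect_true(within_3sigma(fT, 0.8, length(pri)))
    expect_true(within_3sigma(fA, 0.8, length(sec)))
})

test_that("degradation fragments are short, uniform, sense-strand", {
    cfg <- simulationConfig(seed = 17, genomeLengths = c(nuclear = 5000))
    sim <- simulateDegradation(makeReferences(cfg)$genome, "nuclear",
                               cfg, n = 1000)
    lens <- width(sim$reads)
    expect_true(all(lens >= 15L & lens <= 19L))
    expect_true(all(sim$truth$strand == "+"))
    expect_true(all(sim$truth$start >= 1L & sim$truth$end <= 5000L))
})

test_that("mixed library composition matches configured fractions", {
    cfg <- simulationConfig(seed = 19, depth = 1000L,
                            condition = "total")  # degradation 0.8
    lib <- simulateLibrary(cfg)
    cls <- table(lib$truth$class)
    n <- nrow(lib$truth)
    fdeg <- sum(cls["degradation"]) / n
    expect_true(within_3sigma(fdeg, 0.8, n))
    # signal classes contribute ~depth reads each
    expect_equal(unname(cls["dicer_duplex"]), 1000)
    expect_equal(unname(cls["plant_sRNA"]), 1000)
    # enriched default must not exceed total default
    expect_lt(simulationConfig(condition = "enriched")@degradationFraction,
              cfg@degradationFraction)
})

test_that("FASTQ and truth round-trip; fixed seed gives identical bytes", {
    cfg <- simulationConfig(seed = 23, depth = 50L)
    lib <- simulateLibrary(cfg)
    fq <- tempfile(fileext = ".fastq")
    writeLibrary(lib$reads, fq)
    back <- readLibrary(fq)
    expect_identical(length(back), length(lib$reads))
    expect_identical(as.character(back), as.character(lib$reads))
    # empty library -> valid empty file
    fq0 <- tempfile(fileext = ".fastq")
    writeLibrary(Biostrings::DNAStringSet(), fq0)
    expect_identical(length(readLibrary(fq0)), 0L)
    # determinism at byte level
    lib2 <- simulateLibrary(cfg)
    fq2 <- tempfile(fileext = ".fastq")
    writeLibrary(lib2$reads, fq2)
    expect_identical(readLines(fq), readLines(fq2))
    # truth TSV round trip (1-based in memory, 0-based half-open on disk)
    tsv <- tempfile(fileext = ".tsv")
    writeTruth(lib$truth, tsv)
    tr <- readTruth(tsv)
    expect_identical(tr$start, lib$truth$start)
    raw <- read.delim(tsv)
    expect_identical(raw$start, lib$truth$start - 1L)
})

test_that("config validity rejects inconsistent worlds", {
    expect_error(simulationConfig(dicerSizeDist = c(`21` = 0.9)), "sum")
    expect_error(simulationConfig(pingpongOverlap = 26L,
                                  piRNASizeRange = c(25L, 30L)),
                 "exceeds")
    expect_error(simulationConfig(degradationFraction = 1.2), "0,1")
    expect_error(simulationConfig(
        duplexAsymmetry = c(`-3` = 0.5, `0` = 0.5)), "detectab")
})
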