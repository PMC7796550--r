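test_that("depth increments, filters, and mass conservation", {
    a <- c(aln_gr(6, 21, "+", id = "a", seqlen = 100),
           aln_gr(40, 25, "-", id = "b", seqlen = 100))
    prof <- buildCoverage(a, "chr")
    expect_identical(sum(strandDepth(prof, "+") > 0), 21L)
    expect_identical(as.integer(sum(strandDepth(prof, "+"))), 21L)
    expect_identical(as.integer(sum(strandDepth(prof, "-"))), 25L)
    # size filter drops the 25-mer entirely
    p19 <- buildCoverage(a, "chr", sizeRange = c(19, 23))
    expect_identical(as.integer(sum(strandDepth(p19, "-"))), 0L)
    # conservation: total depth mass == total kept aligned bases
    set.seed(193)
    n <- 300
    rnd <- aln_gr(sample(900, n, TRUE), sample(15:31, n, TRUE),
                  sample(c("+", "-"), n, TRUE),
                  id = sprintf("r%03d", seq_len(n)), seqlen = 1000)
    pr <- buildCoverage(rnd, "chr")
    expect_identical(as.integer(sum(strandDepth(pr, "+")) +
                                sum(strandDepth(pr, "-"))),
                     sum(width(rnd)))
    # uniqueness filter keys off n_placements
    mcols(rnd)$n_placements <- rep(c(1L, 3L), length.out = n)
    pu <- buildCoverage(rnd, "chr", uniqueness = "unique")
    pm <- buildCoverage(rnd, "chr", uniqueness = "multi")
    expect_identical(as.integer(sum(strandDepth(pu, "+")) +
                                sum(strandDepth(pu, "-")) +
                                sum(strandDepth(pm, "+")) +
                                sum(strandDepth(pm, "-"))),
                     sum(width(rnd)))
    # fractional weighting divides by placement count
    pw <- buildCoverage(rnd, "chr", weighted = TRUE)
    expect_equal(sum(strandDepth(pw, "+")) + sum(strandDepth(pw, "-")),
                 sum(width(rnd) / mcols(rnd)$n_placements))
})

test_that("dual/single/uncovered partition sums to one exactly", {
    # bases 1-10 plus-only, 11-20 dual
    a <- c(aln_gr(1, 20, "+", id = "p", seqlen = 20),
           aln_gr(11, 10, "-", id = "m", seqlen = 20))
    d <- dualStrandFraction(buildCoverage(a, "chr"))
    expect_identical(d$dual, 0.5)
    expect_identical(d$single, 0.5)
    expect_identical(d$uncovered, 0)
    # empty profile
    d0 <- dualStrandFraction(buildCoverage(a[0], "chr",
                                           contigLength = 20L))
    expect_identical(d0$uncovered, 1)
    set.seed(197)
    n <- 200
    rnd <- aln_gr(sample(900, n, TRUE), sample(15:31, n, TRUE),
                  sample(c("+", "-"), n, TRUE), seqlen = 1000)
    dr <- dualStrandFraction(buildCoverage(rnd, "chr"))
    expect_identical(dr$dual + dr$single + dr$uncovered, 1)
})

test_that("duplex substrates show more dual-strand coverage than decay", {
    cfg <- simulationConfig(seed = 199, genomeLengths = c(trigger = 2000))
    g <- makeReferences(cfg)$genome
    dup <- truthToGRanges(simulateDicerReads(g, "trigger", cfg,
                                             n = 300)$truth)
    deg <- truthToGRanges(simulateDegradation(g, "trigger", cfg, n = 600,
                                              seed = 200)$truth)
    fdup <- dualStrandFraction(buildCoverage(dup, "trigger",
                                             contigLength = 2000L))
    fdeg <- dualStrandFraction(buildCoverage(deg, "trigger",
                                             contigLength = 2000L))
    expect_gte(fdup$dual, fdeg$dual)
    expect_identical(fdeg$dual, 0)   # sense-only fragments never dual
})

test_that("compartment ratio is length-normalised read density", {
    a <- suppressWarnings(c(
        aln_gr(sample(980, 100, TRUE), 20, "+", contig = "plastid",
               id = sprintf("p%03d", 1:100)),
        aln_gr(sample(9980, 100, TRUE), 20, "+", contig = "nuclear",
               id = sprintf("n%03d", 1:100))))
    r <- compartmentRatio(a, c(plastid = 1000, nuclear = 10000))
    expect_identical(r$ratio, 10)
    b <- suppressWarnings(c(
        aln_gr(1:10, 20, "+", contig = "plastid",
               id = sprintf("p%d", 1:10)),
        aln_gr(1:100, 20, "+", contig = "nuclear",
               id = sprintf("n%d", 1:100))))
    expect_identical(compartmentRatio(b, c(plastid = 1000,
                                           nuclear = 10000))$ratio, 1)
    expect_error(compartmentRatio(a[1:100],
                                  c(plastid = 1000, nuclear = 10000)),
                 "denominator")
    # simulated 5x plastid-enriched background recovers the ratio
    cfg <- simulationConfig(seed = 211,
        genomeLengths = c(nuclear = 10000, plastid = 2000))
    g <- makeReferences(cfg)$genome
    n_nuc <- 400
    n_pla <- round(5 * n_nuc * 2000 / 10000)     # 5x per-bp density
    nuc <- simulateDegradation(g, "nuclear", cfg, n_nuc,
                               idPrefix = "n")$truth
    pla <- simulateDegradation(g, "plastid", cfg, n_pla, idPrefix = "p",
                               seed = 212)$truth
    aln <- truthToGRanges(rbind(nuc, pla))
    rr <- compartmentRatio(aln, c(plastid = 2000, nuclear = 10000))
    expect_equal(rr$ratio, 5, tolerance = 0.01)
})

test_that("density tracks tile, conserve and normalise", {
    a <- aln_gr(1, 100, "+", id = "a", seqlen = 100)
    prof <- buildCoverage(a, "chr")
    tr <- densityTrack(prof, window = 20)
    expect_identical(nrow(tr), 5L)
    expect_true(all(tr$density == 20))            # uniform -> constant
    trn <- densityTrack(prof, window = 20, normalize = "max")
    expect_identical(max(trn$density), 1)
    set.seed(223)
    rnd <- aln_gr(sample(900, 100, TRUE), 20, "+", seqlen = 1000)
    pr <- buildCoverage(rnd, "chr")
    tw <- densityTrack(pr, window = 64)
    expect_identical(as.integer(sum(tw$density)),
                     as.integer(sum(strandDepth(pr, "+"))))
    # bedGraph export round-trips total mass
    paths <- writeBedGraph(pr, tempfile())
    bg <- rtracklayer::import(paths[1], format = "bedGraph")
    expect_identical(as.integer(sum(width(bg) * bg$score)),
                     as.integer(sum(strandDepth(pr, "+"))))
})
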