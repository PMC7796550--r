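test_that("pair matrix geometry follows the overlap rule exactly", {
    # 21-mer duplex with 2-nt 3' overhangs: counted from both roles
    a <- c(aln_gr(101, 21, "+", id = "q"), aln_gr(99, 21, "-", id = "p"))
    m <- counts(pairMatrix(a))
    expect_identical(unname(m["21", "21"]), 2L)
    expect_identical(sum(m), 2L)
    # blunt duplex (full overlap, no overhang): not counted
    b <- c(aln_gr(101, 21, "+", id = "q"), aln_gr(101, 21, "-", id = "p"))
    expect_identical(sum(counts(pairMatrix(b))), 0L)
    # asymmetric pair: counted as (21,23) query but not (23,21)
    d <- c(aln_gr(101, 21, "+", id = "q"), aln_gr(103, 23, "-", id = "p"))
    md <- counts(pairMatrix(d))
    expect_identical(unname(md["21", "23"]), 1L)
    expect_identical(unname(md["23", "21"]), 0L)
    # canonical mode keeps the true-duplex register, drops the mirror one
    expect_identical(sum(counts(pairMatrix(a, mode = "canonical"))), 2L)
    expect_identical(sum(counts(pairMatrix(d, mode = "canonical"))), 0L)
    # empty input -> all-zero matrix
    expect_identical(sum(counts(pairMatrix(a[0]))), 0L)
})

test_that("simulated point-mass duplex library concentrates at (21,21)", {
    cfg <- simulationConfig(seed = 89, genomeLengths = c(trigger = 3000),
        dicerSizeDist = c(`21` = 1), duplexAsymmetry = c(`0` = 1))
    sim <- simulateDicerReads(makeReferences(cfg)$genome, "trigger",
                              cfg, n = 500)
    aln <- truthToGRanges(sim$truth)
    m <- counts(pairMatrix(aln))
    expect_gte(unname(m["21", "21"]), 2L * 500L)  # all true pairs, both roles
    offdiag <- sum(m) - m["21", "21"]
    # chance pairs among overlapping duplexes can add mass, but only at 21,21
    expect_identical(unname(offdiag), 0L)
    expect_identical(dicerReadFraction(aln), 1)
})

test_that("pair matrix equals the quadratic all-pairs oracle", {
    for (seed in c(97, 101, 103)) {
        set.seed(seed)
        n <- 400
        aln <- aln_gr(sample(2000, n, TRUE),
                      sample(15:31, n, TRUE),
                      sample(c("+", "-"), n, TRUE),
                      id = sprintf("r%04d", seq_len(n)))
        want <- oracle_pairs(aln)
        got <- pairMatrix(aln)
        expect_identical(unclass(counts(got)), unclass(want$counts),
                         ignore_attr = TRUE)
        frac <- dicerReadFraction(aln)
        expect_equal(frac, length(want$paired_ids) / n)
        # canonical mode agrees with the oracle too
        wc <- oracle_pairs(aln, mode = "canonical")
        expect_identical(unclass(counts(pairMatrix(aln,
            mode = "canonical"))), unclass(wc$counts), ignore_attr = TRUE)
    }
})

test_that("pair matrix is invariant under translation and strand swap", {
    set.seed(107)
    n <- 200
    aln <- aln_gr(sample(1500, n, TRUE), sample(18:24, n, TRUE),
                  sample(c("+", "-"), n, TRUE))
    m0 <- counts(pairMatrix(aln))
    shifted <- GenomicRanges::shift(aln, 137L)
    expect_identical(counts(pairMatrix(shifted)), m0)
    # complement strands and reflect coordinates about a fixed point
    L <- 5000L
    refl <- aln_gr(L - end(aln) + 1L, width(aln),
                   ifelse(as.character(strand(aln)) == "+", "-", "+"),
                   id = mcols(aln)$read_id)
    expect_identical(sum(counts(pairMatrix(refl))), sum(m0))
})

test_that("dicer fraction is monotone in duplex and unpaired reads", {
    cfg <- simulationConfig(seed = 109, genomeLengths = c(trigger = 3000),
                            duplexAsymmetry = c(`0` = 1))
    g <- makeReferences(cfg)$genome
    base <- truthToGRanges(simulateDicerReads(g, "trigger", cfg,
                                              n = 50)$truth)
    more <- truthToGRanges(simulateDicerReads(g, "trigger", cfg, n = 80,
        idPrefix = "extra", seed = 110)$truth)
    f0 <- dicerReadFraction(base)
    expect_gte(dicerReadFraction(c(base, more)), f0)
    # unpaired reads on a separate contig only dilute
    lone <- aln_gr(seq(1, 2000, by = 40), 20, "+", contig = "other",
                   id = sprintf("lone%03d", 1:50))
    expect_lte(dicerReadFraction(suppressWarnings(c(base, lone))), f0)
})

test_that("degradation yields at most the permutation-null fraction", {
    cfg <- simulationConfig(seed = 113, genomeLengths = c(nuclear = 4000))
    sim <- simulateDegradation(makeReferences(cfg)$genome, "nuclear",
                               cfg, n = 400, bothStrands = TRUE)
    aln <- truthToGRanges(sim$truth)
    obs <- dicerReadFraction(aln)
    set.seed(114)
    perm <- replicate(30, {
        shuf <- aln_gr(sample(4000 - 19, length(aln), TRUE), width(aln),
                       as.character(strand(aln)),
                       id = mcols(aln)$read_id, contig = "nuclear")
        dicerReadFraction(shuf)
    })
    expect_lte(obs, mean(perm) + 3 * sd(perm) + 1e-12)
})

test_that("mixed duplex/degradation fraction matches the oracle", {
    cfg <- simulationConfig(seed = 127, genomeLengths = c(trigger = 2500),
                            duplexAsymmetry = c(`0` = 1))
    g <- makeReferences(cfg)$genome
    dup <- truthToGRanges(simulateDicerReads(g, "trigger", cfg,
                                             n = 150)$truth)
    deg <- truthToGRanges(simulateDegradation(g, "trigger", cfg, n = 300,
        bothStrands = TRUE, seed = 128)$truth)
    mix <- c(dup, deg)
    want <- oracle_pairs(mix)
    expect_equal(dicerReadFraction(mix),
                 length(want$paired_ids) /
                     length(unique(mcols(mix)$read_id)))
})

test_that("enrichment ratio and siRNA size fraction behave as defined", {
    expect_identical(dicerEnrichment(0.4, 0.1), 4)
    expect_identical(dicerEnrichment(0.25, 0.25), 1)
    expect_error(dicerEnrichment(0.4, 0), "undefined")
    a21 <- aln_gr(seq(1, 400, 40), 21, "+")
    expect_identical(sirnaSizeFraction(a21), 1)
    a15 <- aln_gr(seq(1, 400, 40), 15, "+")
    expect_identical(sirnaSizeFraction(a15), 0)
    mix <- c(aln_gr(1:6, 21, "+", id = sprintf("a%d", 1:6)),
             aln_gr(101:104, 25, "+", id = sprintf("b%d", 1:4)))
    expect_identical(sirnaSizeFraction(mix), 0.6)
})
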