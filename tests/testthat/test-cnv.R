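# Independent per-position oracle for the sliding median with
# symmetric edge shrinkage.
bruteSlidingMedian <- function(x, k) {
    n <- length(x)
    h <- (k - 1) / 2
    sapply(seq_len(n), function(i) {
        hh <- min(h, i - 1, n - i)
        median(x[(i - hh):(i + hh)])
    })
}

test_that("alignment filtering applies all four removal rules", {
    reads <- data.frame(
        mapped = c(TRUE, FALSE, TRUE, TRUE, TRUE),
        duplicate = c(FALSE, FALSE, TRUE, FALSE, FALSE),
        mapping_score = c(60, 60, 60, 10, 60),
        mismatches = c(0, 0, 0, 0, 2),
        chrom = "chr1", pos = 1:5)
    kept <- filterAlignments(reads, minMappingScore = 30)
    expect_equal(nrow(kept), 1)   # only the fully clean read survives
    # pass-through when everything is clean
    clean <- data.frame(mapped = TRUE, duplicate = FALSE,
                        mapping_score = 60, mismatches = 0,
                        chrom = "chr1", pos = 1:100)
    expect_equal(nrow(filterAlignments(clean, 30)), 100)
    # enumeration: 40 duplicates of 100 leave 60
    dup <- clean
    dup$duplicate <- rep(c(TRUE, FALSE), c(40, 60))
    expect_equal(nrow(filterAlignments(dup, 30)), 60)
})

test_that("reads are assigned to half-open bins by start position", {
    g <- binGrid("chr1", start = c(0, 100), end = c(100, 200),
                 gc = c(0.4, 0.5))
    reads <- data.frame(chrom = "chr1", pos = c(0, 99, 100, 199))
    expect_equal(countReadsPerBin(reads, g), c(2, 2))
    # a read at a bin end belongs to the next bin
    expect_equal(countReadsPerBin(data.frame(chrom = "chr1", pos = 100), g),
                 c(0, 1))
    # off-grid reads are dropped with a tally, not an error
    expect_message(
        out <- countReadsPerBin(
            data.frame(chrom = c("chr1", "chr9"), pos = c(5, 5)), g),
        "dropped 1")
    expect_equal(out, c(1, 0))
})

test_that("uniform reads distribute evenly over equal bins", {
    g <- binGrid("chr1", start = seq(0, 900, 100),
                 end = seq(100, 1000, 100), gc = rep(0.45, 10))
    set.seed(71)
    reads <- data.frame(chrom = "chr1",
                        pos = sample.int(1000, 1000, replace = TRUE) - 1L)
    counts <- countReadsPerBin(reads, g)
    expect_equal(sum(counts), 1000)
    expect_true(all(abs(counts - 100) < 4 * sqrt(100)))
})

test_that("GC normalization is an identity on unbiased counts and
           divides by reference weights", {
    g <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 200,
                          seed = 81)
    flat <- rep(50, 200)
    expect_equal(gcNormalize(flat, g), flat)
    # a doubled reference weight halves that bin's normalized count
    mc <- S4Vectors::mcols(g)
    mc$referenceWeight[7] <- 2
    S4Vectors::mcols(g) <- mc
    g2 <- new("BinGrid", g)
    out <- gcNormalize(flat, g2)
    expect_equal(out[7], 25)
    expect_equal(out[-7], flat[-7])
    expect_error(gcNormalize(rep(0, 200), g), "sample failed")
})

test_that("GC normalization removes a planted quadratic bias", {
    g <- syntheticBinGrid(chromosomes = "chr1",
                          binsPerChromosome = 10000, seed = 91)
    cfg <- simulationConfig(seed = 92, meanReadsPerBin = 200,
                            nbDispersion = 0.02,
                            gcBiasCoefficients = c(1, 0.6, -5))
    x <- simulateBinCounts(g, cfg)
    expect_gt(abs(cor(binGC(g), x)), 0.2)       # bias is really there
    norm <- gcNormalize(x, g)
    expect_lt(abs(cor(binGC(g), norm)), 0.05)   # and normalization kills it
})

test_that("copy-number formula anchors the autosomal median at 2", {
    g <- syntheticBinGrid(chromosomes = paste0("chr", 1:4),
                          binsPerChromosome = 25, seed = 3)
    n <- length(g)
    flat <- rep(40, n)
    expect_equal(copyNumberPerBin(flat, g), rep(2, n))
    # one zero bin keeps copy number 0, no masking
    z <- flat; z[10] <- 0
    expect_equal(copyNumberPerBin(z, g)[10], 0)
    # one chromosome (a minority of bins) at 1.5x the rest: copy 3
    chr4 <- as.character(GenomeInfoDb::seqnames(g)) == "chr4"
    up <- flat
    up[chr4] <- 60
    cn <- copyNumberPerBin(up, g)
    expect_true(all(abs(cn[chr4] - 3) < 1e-9))
    expect_true(all(abs(cn[!chr4] - 2) < 1e-9))
    # exact median-2 anchoring on arbitrary profiles
    for (s in 1:20) {
        set.seed(100 + s)
        x <- rpois(n, 30) + 1
        expect_identical(median(copyNumberPerBin(x, g)), 2)
    }
    expect_error(copyNumberPerBin(rep(0, n), g), "median")
})

test_that("sliding median smooths within chromosomes only", {
    g <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 30,
                          seed = 5)
    expect_equal(smoothCopyNumber(rep(2, 30), g), rep(2, 30))
    spike <- rep(2, 30); spike[15] <- 10
    expect_equal(smoothCopyNumber(spike, g)[15], 2)
    expect_error(smoothCopyNumber(rep(2, 30), g, window = 12), "odd")
    expect_error(smoothCopyNumber(rep(2, 30), g, window = -3), "odd")
    # two chromosomes at different levels stay untouched at the boundary
    g2 <- syntheticBinGrid(chromosomes = c("chrA", "chrB"),
                           binsPerChromosome = 20, seed = 6)
    lv <- rep(c(2, 4), each = 20)
    expect_equal(smoothCopyNumber(lv, g2), lv)
})

test_that("sliding median equals the brute-force oracle", {
    g <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 57,
                          seed = 7)
    set.seed(8)
    for (i in 1:100) {
        x <- runif(57, 0, 4)
        expect_equal(smoothCopyNumber(x, g, 13),
                     bruteSlidingMedian(x, 13))
    }
    # window wider than the chromosome still matches
    g3 <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 9,
                           seed = 9)
    x <- runif(9, 0, 4)
    expect_equal(smoothCopyNumber(x, g3, 13), bruteSlidingMedian(x, 13))
})

test_that("chromosome calls find planted gains and losses", {
    g <- syntheticBinGrid(chromosomes = paste0("chr", 1:6),
                          binsPerChromosome = 40, seed = 10)
    cfg <- simulationConfig(seed = 11)
    for (planted in list(c(chr3 = 3L), c(chr5 = 1L))) {
        x <- simulateBinCounts(g, cfg, planted)
        prof <- callCopyNumber(x, g)
        calls <- chromosomeCalls(prof)
        want <- if (planted == 3L) "gain" else "loss"
        expect_identical(calls$state[calls$chromosome == names(planted)],
                         want)
        expect_true(isAneuploid(prof))
        expect_true(all(calls$state[calls$chromosome != names(planted)] ==
                        "neutral"))
    }
    # flat profile: euploid everywhere
    prof0 <- callCopyNumber(rep(50, length(g)), g, normalize = FALSE)
    expect_false(isAneuploid(prof0))
    expect_true(all(chromosomeCalls(prof0)$medianCn == 2))
})

test_that("sex chromosomes are assessed only with a declared sex", {
    g <- syntheticBinGrid(chromosomes = c("chr1", "chr2", "chrX"),
                          binsPerChromosome = 30, seed = 12)
    chrom <- as.character(GenomeInfoDb::seqnames(g))
    male <- rep(50, length(g)); male[chrom == "chrX"] <- 25
    # without a declared sex: X state NA and excluded from the verdict
    p1 <- callCopyNumber(male, g, normalize = FALSE)
    expect_true(is.na(chromosomeCalls(p1)$state[
        chromosomeCalls(p1)$chromosome == "chrX"]))
    expect_false(isAneuploid(p1))
    # declared male: one X copy is neutral
    p2 <- callCopyNumber(male, g, normalize = FALSE, sex = "male")
    expect_identical(chromosomeCalls(p2)$state[
        chromosomeCalls(p2)$chromosome == "chrX"], "neutral")
    expect_false(isAneuploid(p2))
    # declared female: one X copy is a loss
    p3 <- callCopyNumber(male, g, normalize = FALSE, sex = "female")
    expect_identical(chromosomeCalls(p3)$state[
        chromosomeCalls(p3)$chromosome == "chrX"], "loss")
    expect_true(isAneuploid(p3))
})

test_that("the pipeline is equivariant under count rescaling", {
    g <- syntheticBinGrid(chromosomes = paste0("chr", 1:4),
                          binsPerChromosome = 30, seed = 13)
    x <- simulateBinCounts(g, simulationConfig(seed = 14), c(chr2 = 3))
    a <- callCopyNumber(x, g)
    b <- callCopyNumber(x * 9, g)
    expect_equal(cnPerBin(a), cnPerBin(b))
    expect_equal(smoothedCn(a), smoothedCn(b))
    expect_identical(chromosomeCalls(a)$state, chromosomeCalls(b)$state)
    expect_equal(chromosomeCalls(a)$medianCn,
                 chromosomeCalls(b)$medianCn)
    expect_identical(a@verdict, b@verdict)
})
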