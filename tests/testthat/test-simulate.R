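test_that("cohort generation is reproducible and validates its config", {
    a <- simulateCohort(simulationConfig(nEmbryos = 50, seed = 11))
    b <- simulateCohort(simulationConfig(nEmbryos = 50, seed = 11))
    expect_identical(a, b)
    c <- simulateCohort(simulationConfig(nEmbryos = 50, seed = 12))
    expect_false(identical(a$true_mt_rq, c$true_mt_rq))

    expect_error(simulationConfig(nEmbryos = 0), "positive count")
    expect_error(simulationConfig(ageWeights = numeric(0)), "non-empty")
    expect_error(simulationConfig(aneuploidyEffect = -1), "positive")
})

test_that("cohort structure follows the generative rules", {
    cfg <- simulationConfig(nEmbryos = 302, seed = 21)
    co <- simulateCohort(cfg)
    expect_equal(nrow(co), 302)
    expect_true(all(co$maternal_age >= 26 & co$maternal_age <= 42))
    # aneuploid chromosome list non-empty iff aneuploid
    expect_identical(co$aneuploid_chromosomes != "", co$ploidy == "aneuploid")
    # only euploid embryos receive a transfer outcome
    expect_true(all(co$outcome[co$ploidy == "aneuploid"] == "unknown"))
    # latent fraction is the monotone image of the latent RQ
    expect_equal(co$true_mt_fraction,
                 pmin(rqToMitoPercent(co$true_mt_rq) / 100, 1))
})

test_that("implanted embryos never reach the viability cutoff", {
    for (s in 31:40) {
        cfg <- simulationConfig(nEmbryos = 150, seed = s)
        co <- simulateCohort(cfg)
        expect_true(all(co$true_mt_rq[co$outcome == "implanted"] < 0.003))
    }
})

test_that("zero elevated fraction keeps every euploid below the cutoff", {
    cfg <- simulationConfig(nEmbryos = 200, seed = 5,
                            nonimplanterElevatedFraction = 0,
                            aneuploidyRateByAge =
                                stats::setNames(rep(0, 17), 26:42))
    co <- simulateCohort(cfg)
    expect_true(all(co$true_mt_rq < 0.003))
})

test_that("elevated non-implanter share matches its binomial target", {
    # Monte-Carlo oracle: pooled share over replicate cohorts
    above <- 0L; total <- 0L
    for (s in 1:40) {
        co <- simulateCohort(simulationConfig(nEmbryos = 302, seed = s))
        ni <- co$true_mt_rq[co$ploidy == "euploid" &
                            co$outcome == "not_implanted"]
        above <- above + sum(ni > 0.003)
        total <- total + length(ni)
    }
    phat <- above / total
    se <- sqrt(0.3 * 0.7 / total)
    expect_lt(abs(phat - 0.30), 4 * se)
})

test_that("noise-free qPCR simulation hits the ddCt identities", {
    cfg <- simulationConfig(ctNoiseSd = 0, seed = 3)
    # trueRq = 1: test delta-Ct equals the reference delta-Ct exactly
    ct <- simulateQpcr(1, cfg, referenceDeltaCt = 8)
    dct <- deltaCt(mean(as.numeric(ct[ct$assay == "mt", 3:5])),
                   mean(as.numeric(ct[ct$assay == "alu", 3:5])))
    expect_equal(dct, 8)
    expect_equal(relativeQuantity(dct, 8)$rq, 1)
    # trueRq = 2^-8: ddCt is 8 exactly
    ct <- simulateQpcr(0.00390625, cfg, referenceDeltaCt = 8)
    rq <- quantifyCtTable(ct, referenceDeltaCt = 8)
    expect_equal(rq$delta_delta_ct, 8)
    expect_equal(rq$rq, 0.00390625)
})

test_that("noisy qPCR recovers the planted quantity on average", {
    cfg <- simulationConfig(ctNoiseSd = 0.25, seed = 7)
    rec <- vapply(1:500, function(i) {
        ct <- simulateQpcr(0.003, cfg, referenceDeltaCt = 8, index = i)
        quantifyCtTable(ct, referenceDeltaCt = 8)$rq
    }, numeric(1))
    expect_lt(abs(median(rec) - 0.003) / 0.003, 0.05)
})

test_that("bin-count expectation matches its closed form", {
    g <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 8,
                          seed = 41)
    cfg <- simulationConfig(seed = 42, nbDispersion = 0.1,
                            meanReadsPerBin = 50)
    mu <- 50 * gcBiasCurve(binGC(g), cfg@gcBiasCoefficients) *
        referenceWeights(g)
    draws <- vapply(1:1000, function(i)
        as.numeric(simulateBinCounts(g, cfg, index = i)),
        numeric(length(g)))
    m <- rowMeans(draws)
    se <- sqrt((mu + 0.1 * mu^2) / 1000)
    expect_true(all(abs(m - mu) < 3.5 * se))
})

test_that("Poisson limit gives a flat euploid expectation", {
    g <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 200,
                          seed = 1)
    cfg <- simulationConfig(seed = 2, nbDispersion = 0,
                            gcBiasCoefficients = c(1, 0, 0),
                            meanReadsPerBin = 50)
    x <- simulateBinCounts(g, cfg)
    expect_true(is.numeric(x) && all(x >= 0))
    expect_lt(abs(mean(x) - 50), 3 * sqrt(50 / 200))
    # zero-read bins are permitted and kept
    cfgLow <- simulationConfig(seed = 3, meanReadsPerBin = 0.5,
                               nbDispersion = 0)
    expect_true(any(simulateBinCounts(g, cfgLow) == 0))
})

test_that("planted trisomy shifts the count ratio to 1.5", {
    g <- syntheticBinGrid(chromosomes = c("chr1", "chr2", "chr21"),
                          binsPerChromosome = 30, seed = 51)
    # flat expectation (no GC bias) so the mean/median ratio is clean
    cfg <- simulationConfig(seed = 52, gcBiasCoefficients = c(1, 0, 0),
                            nbDispersion = 0.02)
    chrom <- as.character(GenomeInfoDb::seqnames(g))
    ratios <- vapply(1:200, function(i) {
        x <- simulateBinCounts(g, cfg, c(chr21 = 3), index = i)
        mean(x[chrom == "chr21"]) / median(x[chrom != "chr21"])
    }, numeric(1))
    expect_lt(abs(mean(ratios) - 1.5), 0.05)
})

test_that("mito pileup has the designed depth and planted fractions", {
    cfg <- simulationConfig(seed = 61)
    p <- simulateMitoPileup(cfg, nSites = 2000, depthMean = 150)
    expect_lt(abs(mean(p$ref_count + p$alt_count) - 150),
              3 * sqrt(150 / 2000))
    # no planted sites, zero error rate: no alternate bases at all
    cfg0 <- simulationConfig(seed = 62, errorRate = 0)
    p0 <- simulateMitoPileup(cfg0, nSites = 500, depthMean = 150)
    expect_true(all(p0$alt_count == 0))
    # planted fraction 0.5 recovered within 2% over 500 replicates
    est <- vapply(1:500, function(i) {
        pp <- simulateMitoPileup(cfg, nSites = 5, depthMean = 150,
            plantedHeteroplasmies = data.frame(position = 3,
                                               fraction = 0.5),
            index = i)
        pp$alt_count[3] / (pp$ref_count[3] + pp$alt_count[3])
    }, numeric(1))
    expect_lt(abs(mean(est) - 0.5), 0.02 * 0.5 + 3 * sd(est) / sqrt(500))
    # out-of-range planted site is an error
    expect_error(simulateMitoPileup(cfg, nSites = 10,
        plantedHeteroplasmies = data.frame(position = 11,
                                           fraction = 0.3)),
        "out of range")
})
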