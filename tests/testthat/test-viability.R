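test_that("threshold derivation rounds up from the implanter maximum", {
    # reference-sample implanters peak at 0.00217
    t3 <- data.frame(value = refSamples$rq_qpcr,
                     outcome = refSamples$outcome)
    m <- deriveThreshold(t3, roundingGrid = 0.0005)
    expect_equal(m@trainingMaxImplanter, 0.00217)
    expect_equal(cutoff(m), 0.0025)
    expect_equal(cutoff(deriveThreshold(t3, roundingGrid = 0.003)), 0.003)
    # an exact multiple still rounds strictly up
    d <- data.frame(value = c(0.002, 0.004),
                    outcome = c("implanted", "not_implanted"))
    expect_equal(cutoff(deriveThreshold(d, roundingGrid = 0.001)), 0.003)
    # separable case: the cutoff separates the groups perfectly
    sep <- data.frame(value = c(0.001, 0.0015, 0.004, 0.006),
                      outcome = c("implanted", "implanted",
                                  "not_implanted", "not_implanted"))
    ms <- deriveThreshold(sep, roundingGrid = 0.0005)
    expect_identical(classifyViability(sep$value, ms),
                     ifelse(sep$outcome == "implanted",
                            "potentially_viable", "predicted_nonviable"))
    expect_error(deriveThreshold(
        data.frame(value = 1, outcome = "not_implanted")),
        "fixedThreshold")
    expect_error(deriveThreshold(
        data.frame(value = 1, outcome = "implanted")),
        "both outcomes")
})

test_that("viability classification is strict at the cutoff", {
    m <- fixedThreshold(0.003, "qpcr")
    expect_identical(classifyViability(0.00426, m), "predicted_nonviable")
    expect_identical(classifyViability(0.000131, m), "potentially_viable")
    expect_identical(classifyViability(0.003, m), "potentially_viable")
    expect_error(classifyViability(0, m), "positive")
})

test_that("cohort evaluation reproduces the retrospective metrics", {
    m <- fixedThreshold(0.003, "qpcr")
    metrics <- evaluateCohort(retrospectiveCohort(), m)
    expect_equal(npv(metrics), 100)
    expect_equal(metrics@flaggedNonimplanterFraction, 100 * 14 / 47)
    expect_equal(metrics@nAbove, 14)
    expect_equal(metrics@nImplanted, 42)
    # nobody above the cutoff: NPV not applicable, nothing flagged
    low <- data.frame(value = c(0.001, 0.002),
                      outcome = c("implanted", "not_implanted"))
    m0 <- evaluateCohort(low, m)
    expect_true(is.na(npv(m0)))
    expect_equal(m0@flaggedNonimplanterFraction, 0)
    # unknown outcomes are excluded with a tally
    withUnknown <- rbind(low, data.frame(value = 0.01,
                                         outcome = "unknown"))
    expect_message(mu <- evaluateCohort(withUnknown, m), "excluding 1")
    expect_equal(mu@nTransferred, 2)
})

test_that("cohort metrics equal a brute-force recount on random cohorts", {
    m <- fixedThreshold(0.003, "qpcr")
    set.seed(19)
    for (i in 1:200) {
        n <- sample(5:60, 1)
        d <- data.frame(
            value = exp(runif(n, log(2e-4), log(2e-2))),
            outcome = sample(c("implanted", "not_implanted"), n,
                             replace = TRUE))
        if (length(unique(d$outcome)) < 2) next
        got <- evaluateCohort(d, m)
        above <- d$value > 0.003
        impl <- d$outcome == "implanted"
        expect_equal(got@nAbove, sum(above))
        expect_equal(got@nAboveImplanted, sum(above & impl))
        expect_equal(got@rateOverall, 100 * mean(impl))
        if (sum(above) > 0)
            expect_equal(npv(got),
                         100 * sum(above & !impl) / sum(above))
        expect_equal(got@flaggedNonimplanterFraction,
                     100 * sum(above & !impl) / sum(!impl))
    }
})

test_that("metrics are invariant to order and whole-cohort duplication", {
    m <- fixedThreshold(0.003, "qpcr")
    d <- retrospectiveCohort()
    set.seed(20)
    shuffled <- d[sample.int(nrow(d)), ]
    a <- evaluateCohort(d, m)
    b <- evaluateCohort(shuffled, m)
    expect_equal(metricsAsList(a), metricsAsList(b))
    doubled <- evaluateCohort(rbind(d, d), m)
    expect_equal(doubled@nAbove, 2 * a@nAbove)
    expect_equal(npv(doubled), npv(a))
    expect_equal(doubled@rateOverall, a@rateOverall)
    expect_equal(doubled@flaggedNonimplanterFraction,
                 a@flaggedNonimplanterFraction)
})

test_that("blinded validation reproduces the prospective metrics", {
    res <- blindedValidate(retrospectiveCohort(), prospectiveCohort(),
                           model = fixedThreshold(0.003, "qpcr"))
    expect_equal(npv(res$metrics), 100)
    expect_equal(res$metrics@rateBelow, 100 * 16 / 27)
    expect_equal(res$metrics@rateOverall, 100 * 16 / 42)
    expect_equal(res$metrics@nAbove, 15)
})

test_that("blinding is enforced and the degenerate split matches
           retrospective evaluation", {
    d <- retrospectiveCohort()
    overlap <- d
    overlap$embryo_id[1] <- "P01"
    expect_error(blindedValidate(overlap, prospectiveCohort(),
                                 model = fixedThreshold(0.003, "qpcr")),
                 "blinding violated")
    # identical train/test content under fresh ids equals the
    # retrospective evaluation
    test <- d
    test$embryo_id <- sprintf("Q%02d", seq_len(nrow(d)))
    res <- blindedValidate(d, test, roundingGrid = 0.0005)
    expect_equal(metricsAsList(res$metrics),
                 metricsAsList(evaluateCohort(d, res$model)))
})

test_that("derived thresholds never flag a training implanter", {
    for (s in 41:60) {
        co <- simulateCohort(transferConfig(seed = s))
        d <- data.frame(value = co$true_mt_rq, outcome = co$outcome)
        m <- deriveThreshold(d, roundingGrid = 0.0005)
        expect_equal(npv(evaluateCohort(d, m)), 100)
    }
})
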