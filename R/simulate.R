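#' @include AllClasses.R utils.R
NULL

# Per-age cohort composition of the 302-blastocyst reference cohort:
# total embryos and aneuploid embryos per year of maternal age.
.defaultAgeCounts <- c(
    "26" = 1, "29" = 1, "30" = 14, "31" = 12, "32" = 10, "33" = 12,
    "34" = 9, "35" = 12, "36" = 35, "37" = 41, "38" = 34, "39" = 36,
    "40" = 26, "41" = 31, "42" = 28)

.defaultAneuploidCounts <- c(
    "26" = 0, "29" = 0, "30" = 5, "31" = 3, "32" = 3, "33" = 3,
    "34" = 1, "35" = 2, "36" = 9, "37" = 12, "38" = 6, "39" = 18,
    "40" = 7, "41" = 15, "42" = 15)

#' Create a synthetic-cohort configuration
#'
#' Builds a [SimulationConfig-class] holding every tunable of the
#' synthetic trophectoderm-biopsy generator. The defaults are the study
#' conditions the downstream statistics assume; see the vignette for a
#' discussion of each choice.
#'
#' @param nEmbryos cohort size (default 302, the size of the reference
#'   blastocyst cohort).
#' @param ageWeights named numeric vector of per-age sampling weights
#'   (names are maternal ages in years). Defaults to the per-age embryo
#'   counts of the reference cohort (ages 26-42).
#' @param aneuploidyRateByAge named numeric vector of per-age aneuploidy
#'   probabilities; defaults to the per-age aneuploid fractions of the
#'   reference cohort.
#' @param cleavageFraction probability that an embryo is sampled at
#'   cleavage stage rather than blastocyst stage (default 0).
#' @param blastocystAgeEffect multiplicative change in latent relative
#'   mtDNA quantity (RQ) per year of maternal age at blastocyst stage
#'   (> 1; default 1.10).
#' @param cleavageAgeEffect per-year multiplicative factor at cleavage
#'   stage (< 1; default 0.90 - cleavage-stage mtDNA falls with age).
#' @param aneuploidyEffect multiplicative RQ elevation in aneuploid
#'   embryos (default 1.8).
#' @param implantationRate probability that a transferred euploid embryo
#'   implants before the mtDNA constraint is imposed (default 0.47,
#'   i.e. 42 of 89 in the retrospective transfer cohort).
#' @param nonimplanterElevatedFraction share of euploid non-implanting
#'   blastocysts whose RQ is resampled above the viability cutoff
#'   (default 0.30).
#' @param viabilityCutoff latent RQ viability threshold (default 0.003);
#'   implanting blastocysts never exceed it by construction.
#' @param rqBaseline median RQ of a euploid blastocyst at
#'   `referenceAge` (default 0.0015).
#' @param cleavageRqBaseline median RQ of a euploid cleavage-stage
#'   blastomere at `referenceAge` (default 0.05; blastomeres carry far
#'   more mtDNA than few-cell trophectoderm biopsies).
#' @param referenceAge age anchoring the baselines (default 34).
#' @param rqLognormalSigma standard deviation of latent log RQ (natural
#'   log scale; default 1.0, spanning roughly two orders of magnitude
#'   within an age group).
#' @param ctNoiseSd per-replicate Gaussian noise on simulated cycle
#'   thresholds, in cycles (default 0.15).
#' @param aluCtBaseline mean cycle threshold of the multicopy Alu assay
#'   (default 14 cycles).
#' @param nbDispersion negative-binomial dispersion of per-bin read
#'   counts (variance = mu + dispersion * mu^2; 0 gives Poisson;
#'   default 0.1, reflecting whole-genome-amplification overdispersion).
#' @param gcBiasCoefficients quadratic GC-bias curve `c(intercept,
#'   slope, quadratic)` evaluated in `gc - 0.45` (default
#'   `c(1, 0, -4)`, a unimodal bias peaking at mid GC).
#' @param meanReadsPerBin expected reads per bin at copy number 2 with
#'   no bias (default 50).
#' @param errorRate per-base sequencing error rate used for
#'   non-heteroplasmic pileup sites (default 0.002).
#' @param seed integer master seed; every generator derives a
#'   deterministic substream from it. `NA` leaves the RNG state alone.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nEmbryos = 50, seed = 1)
#' cohort <- simulateCohort(cfg)
#' table(cohort$ploidy)
#' @export
simulationConfig <- function(nEmbryos = 302,
                             ageWeights = .defaultAgeCounts,
                             aneuploidyRateByAge =
                                 .defaultAneuploidCounts / .defaultAgeCounts,
                             cleavageFraction = 0,
                             blastocystAgeEffect = 1.10,
                             cleavageAgeEffect = 0.90,
                             aneuploidyEffect = 1.8,
                             implantationRate = 0.47,
                             nonimplanterElevatedFraction = 0.30,
                             viabilityCutoff = 0.003,
                             rqBaseline = 0.0015,
                             cleavageRqBaseline = 0.05,
                             referenceAge = 34,
                             rqLognormalSigma = 1.0,
                             ctNoiseSd = 0.15,
                             aluCtBaseline = 14,
                             nbDispersion = 0.1,
                             gcBiasCoefficients = c(1, 0, -4),
                             meanReadsPerBin = 50,
                             errorRate = 0.002,
                             seed = NA_real_) {
    new("SimulationConfig",
        nEmbryos = nEmbryos, ageWeights = ageWeights,
        aneuploidyRateByAge = aneuploidyRateByAge,
        cleavageFraction = cleavageFraction,
        blastocystAgeEffect = blastocystAgeEffect,
        cleavageAgeEffect = cleavageAgeEffect,
        aneuploidyEffect = aneuploidyEffect,
        implantationRate = implantationRate,
        nonimplanterElevatedFraction = nonimplanterElevatedFraction,
        viabilityCutoff = viabilityCutoff, rqBaseline = rqBaseline,
        cleavageRqBaseline = cleavageRqBaseline,
        referenceAge = referenceAge,
        rqLognormalSigma = rqLognormalSigma, ctNoiseSd = ctNoiseSd,
        aluCtBaseline = aluCtBaseline, nbDispersion = nbDispersion,
        gcBiasCoefficients = gcBiasCoefficients,
        meanReadsPerBin = meanReadsPerBin, errorRate = errorRate,
        seed = as.numeric(seed))
}

# Truncated log-normal draws via inverse-CDF (exact, no rejection).
.rlnormTrunc <- function(n, meanlog, sdlog, cutoff, side) {
    zc <- (log(cutoff) - meanlog) / sdlog
    p <- pmin(pmax(pnorm(zc), 1e-12), 1 - 1e-12)
    u <- runif(n)
    z <- if (side == "below") qnorm(u * p) else qnorm(p + u * (1 - p))
    exp(meanlog + sdlog * z)
}

#' Map a qPCR relative quantity to the NGS mitochondrial percent
#'
#' Deterministic monotone link between the two assay scales, chosen to
#' pass through the paired viability thresholds (relative quantity
#' 0.003 maps to 0.07 percent of aligned bases):
#' `percent = 0.07 / sqrt(0.003) * sqrt(rq)`. The square-root exponent
#' matches the log-log slope of paired published sample values.
#'
#' @param rq positive relative quantity (2^-ddCt scale).
#' @return NGS mitochondrial fraction, in percent of aligned bases.
#' @examples
#' rqToMitoPercent(0.003)  # 0.07 by construction
#' @export
rqToMitoPercent <- function(rq) {
    stopifnot(all(rq > 0))
    0.07 / sqrt(0.003) * sqrt(rq)
}

#' Simulate an embryo cohort
#'
#' Draws a cohort of embryo records with the generative structure the
#' downstream analyses assume: maternal ages from `ageWeights`, ploidy
#' from the per-age aneuploidy rates, and a latent relative mtDNA
#' quantity (`true_mt_rq`) drawn log-normally around a stage-dependent
#' age trend (rising with age for blastocysts, falling for cleavage
#' stage), multiplied by `aneuploidyEffect` for aneuploid embryos.
#' Euploid blastocysts receive a transfer outcome: implanting embryos
#' have their RQ constrained below `viabilityCutoff`, and a fraction
#' `nonimplanterElevatedFraction` of non-implanters is resampled above
#' it. Aneuploid embryos are never transferred (outcome `"unknown"`).
#' Cleavage-stage records receive outcomes without any RQ coupling,
#' matching the absence of an outcome association at that stage.
#'
#' @param config a [SimulationConfig-class].
#' @return a `data.frame` with one row per embryo: `embryo_id`,
#'   `maternal_age`, `stage`, `ploidy`, `aneuploid_chromosomes`
#'   (semicolon-separated `chrom:copies`, empty for euploid),
#'   `outcome`, `true_mt_rq`, `true_mt_fraction`.
#' @examples
#' cohort <- simulateCohort(simulationConfig(nEmbryos = 20, seed = 7))
#' head(cohort)
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    .maybeSeed(config@seed, "cohort")
    n <- as.integer(config@nEmbryos)
    ages <- as.integer(sample(names(config@ageWeights), n, replace = TRUE,
                              prob = config@ageWeights))
    stage <- ifelse(runif(n) < config@cleavageFraction,
                    "cleavage", "blastocyst")
    rate <- config@aneuploidyRateByAge[as.character(ages)]
    rate[is.na(rate)] <- 0
    ploidy <- ifelse(stage == "blastocyst" & runif(n) < rate,
                     "aneuploid", "euploid")
    aneuChrom <- vapply(seq_len(n), function(i) {
        if (ploidy[i] != "aneuploid") return("")
        k <- sample(1:2, 1L, prob = c(0.8, 0.2))
        chroms <- sample(paste0("chr", 1:22), k)
        copies <- sample(c(1L, 3L), k, replace = TRUE)
        paste(sprintf("%s:%d", chroms, copies), collapse = ";")
    }, character(1))

    ageEff <- ifelse(stage == "blastocyst",
                     log(config@blastocystAgeEffect),
                     log(config@cleavageAgeEffect))
    base <- ifelse(stage == "blastocyst",
                   log(config@rqBaseline), log(config@cleavageRqBaseline))
    meanlog <- base + (ages - config@referenceAge) * ageEff +
        ifelse(ploidy == "aneuploid", log(config@aneuploidyEffect), 0)
    rq <- exp(rnorm(n, meanlog, config@rqLognormalSigma))

    outcome <- rep("unknown", n)
    transferred <- ploidy == "euploid"
    outcome[transferred] <- ifelse(
        runif(sum(transferred)) < config@implantationRate,
        "implanted", "not_implanted")

    # Viability coupling (blastocyst stage only): implanters sit below
    # the cutoff; a set share of non-implanters is elevated above it.
    blast <- stage == "blastocyst"
    impl <- which(blast & outcome == "implanted")
    if (length(impl))
        rq[impl] <- .rlnormTrunc(length(impl), meanlog[impl],
                                 config@rqLognormalSigma,
                                 config@viabilityCutoff, "below")
    noimpl <- which(blast & outcome == "not_implanted")
    if (length(noimpl)) {
        elevated <- runif(length(noimpl)) <
            config@nonimplanterElevatedFraction
        side <- ifelse(elevated, "above", "below")
        for (s in c("above", "below")) {
            idx <- noimpl[side == s]
            if (length(idx))
                rq[idx] <- .rlnormTrunc(length(idx), meanlog[idx],
                                        config@rqLognormalSigma,
                                        config@viabilityCutoff, s)
        }
    }

    data.frame(
        embryo_id = sprintf("E%04d", seq_len(n)),
        maternal_age = ages,
        stage = stage,
        ploidy = ploidy,
        aneuploid_chromosomes = aneuChrom,
        outcome = outcome,
        true_mt_rq = rq,
        true_mt_fraction = pmin(rqToMitoPercent(rq) / 100, 1),
        stringsAsFactors = FALSE)
}

#' Simulate triplicate qPCR cycle thresholds for one sample
#'
#' Generates mitochondrial and Alu triplicates consistent with the
#' ddCt model: the Alu assay amplifies around `aluCtBaseline`, and the
#' mitochondrial cycle threshold sits `referenceDeltaCt - log2(trueRq)`
#' cycles later, so that quantifying the output with
#' [relativeQuantity()] against `referenceDeltaCt` recovers `trueRq`
#' exactly when `ctNoiseSd = 0`. Each replicate is perturbed by
#' independent Gaussian noise of `ctNoiseSd` cycles.
#'
#' @param trueRq latent relative mtDNA quantity (> 0).
#' @param config a [SimulationConfig-class] (noise, Alu baseline, seed).
#' @param referenceDeltaCt the run-constant reference sample's delta-Ct
#'   (Ct_mt - Ct_alu), in cycles.
#' @param embryoId sample identifier written into the output.
#' @param index substream index, used by [simulateQpcrTable()] to give
#'   each record its own reproducible draw.
#' @return a two-row `data.frame` (`embryo_id`, `assay` in
#'   `{"mt","alu"}`, `rep1`, `rep2`, `rep3`).
#' @examples
#' cfg <- simulationConfig(ctNoiseSd = 0, seed = 1)
#' simulateQpcr(1, cfg, referenceDeltaCt = 8)
#' @export
simulateQpcr <- function(trueRq, config, referenceDeltaCt = 8,
                         embryoId = "sample", index = 0L) {
    .assertScalarNumber(trueRq, "trueRq", positive = TRUE)
    stopifnot(is(config, "SimulationConfig"))
    .maybeSeed(config@seed, "qpcr", index)
    aluTrue <- config@aluCtBaseline
    mtTrue <- aluTrue + referenceDeltaCt - log2(trueRq)
    alu <- aluTrue + rnorm(3L, 0, config@ctNoiseSd)
    mt <- mtTrue + rnorm(3L, 0, config@ctNoiseSd)
    data.frame(embryo_id = embryoId, assay = c("mt", "alu"),
               rep1 = c(mt[1L], alu[1L]), rep2 = c(mt[2L], alu[2L]),
               rep3 = c(mt[3L], alu[3L]), stringsAsFactors = FALSE)
}

#' Simulate a cohort's qPCR Ct table
#'
#' Applies [simulateQpcr()] to every row of a simulated cohort, with a
#' per-record substream derived from the configured master seed.
#'
#' @param records cohort `data.frame` from [simulateCohort()] (needs
#'   `embryo_id` and `true_mt_rq`).
#' @inheritParams simulateQpcr
#' @return a long `data.frame`, two rows (mt, alu) per embryo.
#' @export
simulateQpcrTable <- function(records, config, referenceDeltaCt = 8) {
    stopifnot(all(c("embryo_id", "true_mt_rq") %in% names(records)))
    out <- lapply(seq_len(nrow(records)), function(i)
        simulateQpcr(records$true_mt_rq[i], config, referenceDeltaCt,
                     embryoId = records$embryo_id[i], index = i))
    do.call(rbind, out)
}

#' Quadratic GC-bias curve
#'
#' Relative coverage multiplier as a function of bin GC fraction:
#' `max(c0 + c1 * (gc - 0.45) + c2 * (gc - 0.45)^2, 0.05)`.
#'
#' @param gc GC fractions in `[0, 1]`.
#' @param coefficients numeric length-3 `c(intercept, slope, quadratic)`.
#' @return positive multipliers, one per input GC value.
#' @export
gcBiasCurve <- function(gc, coefficients = c(1, 0, -4)) {
    stopifnot(length(coefficients) == 3L)
    x <- gc - 0.45
    pmax(coefficients[1L] + coefficients[2L] * x + coefficients[3L] * x^2,
         0.05)
}

.parseAneuploidies <- function(x) {
    if (is.null(x) || length(x) == 0L) return(integer(0))
    if (is.numeric(x)) {
        stopifnot(!is.null(names(x)), all(x %in% c(1, 3)))
        return(stats::setNames(as.integer(x), names(x)))
    }
    x <- x[nzchar(x)]
    if (!length(x)) return(integer(0))
    parts <- strsplit(unlist(strsplit(x, ";", fixed = TRUE)), ":",
                      fixed = TRUE)
    states <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
    names(states) <- vapply(parts, `[`, character(1), 1L)
    if (!all(states %in% c(1L, 3L)))
        stop("aneuploid copy states must be 1 (monosomy) or 3 (trisomy)")
    states
}

#' Simulate per-bin read counts for one sample
#'
#' Draws negative-binomial read counts over a [BinGrid-class] with
#' per-bin expectation
#' `meanReadsPerBin * (copies / 2) * gcBias(gc) * referenceWeight`,
#' where `copies` is 2 except on chromosomes listed in
#' `aneuploidChromosomes` (1 for monosomy, 3 for trisomy). With
#' `nbDispersion = 0` counts are Poisson. Zero-count bins are retained.
#'
#' @param grid a [BinGrid-class].
#' @param config a [SimulationConfig-class] (depth, dispersion, GC-bias
#'   curve, seed).
#' @param aneuploidChromosomes either a named integer vector
#'   (`c(chr21 = 3)`) or the serialized `"chr21:3;chr16:1"` form used
#'   in cohort tables; `NULL` or `""` for euploid.
#' @param index substream index for per-record reproducibility.
#' @return integer vector of counts, one per bin.
#' @examples
#' g <- syntheticBinGrid(chromosomes = c("chr1", "chr21"),
#'                       binsPerChromosome = 10, seed = 1)
#' cfg <- simulationConfig(seed = 1)
#' simulateBinCounts(g, cfg, aneuploidChromosomes = c(chr21 = 3))
#' @export
simulateBinCounts <- function(grid, config, aneuploidChromosomes = NULL,
                              index = 0L) {
    stopifnot(is(grid, "BinGrid"), is(config, "SimulationConfig"))
    if (length(grid) == 0L) stop("bin grid is empty")
    .maybeSeed(config@seed, "bincounts", index)
    states <- .parseAneuploidies(aneuploidChromosomes)
    copies <- rep(2, length(grid))
    if (length(states)) {
        chrom <- as.character(seqnames(grid))
        for (chr in names(states)) copies[chrom == chr] <- states[[chr]]
    }
    mu <- config@meanReadsPerBin * (copies / 2) *
        gcBiasCurve(binGC(grid), config@gcBiasCoefficients) *
        referenceWeights(grid)
    if (config@nbDispersion <= 1e-12)
        rpois(length(grid), mu)
    else
        rnbinom(length(grid), mu = mu, size = 1 / config@nbDispersion)
}

#' Simulate a mitochondrial pileup
#'
#' Per-site depths are Poisson with mean `depthMean` (the sequencing
#' design targets roughly 150x over the 16.6 kb mitochondrial genome);
#' alternate-allele counts are binomial with the planted heteroplasmy
#' fraction at planted sites and the sequencing `errorRate` elsewhere.
#'
#' @param config a [SimulationConfig-class] (error rate, seed).
#' @param nSites number of mitochondrial positions (default 16569, the
#'   full genome).
#' @param depthMean mean per-site read depth (default 150).
#' @param plantedHeteroplasmies `data.frame` with columns `position`
#'   (1-based, within `nSites`) and `fraction` (in (0, 1)), or `NULL`.
#' @param index substream index for per-record reproducibility.
#' @return a `data.frame` (`position`, `ref_count`, `alt_count`).
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' p <- simulateMitoPileup(cfg, nSites = 100, depthMean = 150,
#'     plantedHeteroplasmies = data.frame(position = 10, fraction = 0.3))
#' p[10, ]
#' @export
simulateMitoPileup <- function(config, nSites = 16569L, depthMean = 150,
                               plantedHeteroplasmies = NULL, index = 0L) {
    stopifnot(is(config, "SimulationConfig"))
    .assertScalarNumber(depthMean, "depthMean", positive = TRUE)
    nSites <- as.integer(nSites)
    stopifnot(nSites >= 1L)
    rate <- rep(config@errorRate, nSites)
    if (!is.null(plantedHeteroplasmies) && nrow(plantedHeteroplasmies)) {
        pos <- plantedHeteroplasmies$position
        frac <- plantedHeteroplasmies$fraction
        if (any(pos < 1L | pos > nSites))
            stop("planted heteroplasmy site index out of range")
        if (any(frac <= 0 | frac >= 1))
            stop("planted heteroplasmy fractions must lie in (0, 1)")
        rate[pos] <- frac
    }
    .maybeSeed(config@seed, "pileup", index)
    depth <- rpois(nSites, depthMean)
    alt <- rbinom(nSites, depth, rate)
    data.frame(position = seq_len(nSites), ref_count = depth - alt,
               alt_count = alt)
}
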