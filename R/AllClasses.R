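#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Genomic bin grid for read-depth copy-number analysis
#'
#' A \code{BinGrid} is a \linkS4class{GRanges} whose metadata columns carry,
#' per bin, the GC fraction (\code{gc}), the number of uniquely mapping
#' 36-mers the bin was built to contain (\code{mappable36mers}, 100 on
#' canonical grids), and a positive in-silico reference weight
#' (\code{referenceWeight}, the expected relative coverage of the bin in a
#' normal reference data set, median-1 scaled). Bins must be sorted by
#' (chromosome, start) and non-overlapping within a chromosome.
#'
#' On disk the grid is a BED-like TSV with 0-based half-open coordinates
#' (see [readBinGrid()]); in memory coordinates follow the usual 1-based
#' closed \code{GRanges} convention.
#'
#' @seealso [binGrid()], [syntheticBinGrid()], [countReadsPerBin()]
#' @export
setClass("BinGrid", contains = "GRanges")

setValidity("BinGrid", function(object) {
    msg <- character()
    mc <- mcols(object)
    need <- c("gc", "mappable36mers", "referenceWeight")
    missing <- setdiff(need, colnames(mc))
    if (length(missing))
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    if (any(mc$gc < 0 | mc$gc > 1, na.rm = TRUE))
        msg <- c(msg, "'gc' must lie in [0, 1]")
    if (any(mc$referenceWeight <= 0, na.rm = TRUE))
        msg <- c(msg, "'referenceWeight' must be positive")
    if (any(mc$mappable36mers < 0, na.rm = TRUE))
        msg <- c(msg, "'mappable36mers' must be non-negative")
    if (length(object) > 1L) {
        if (!identical(BiocGenerics::order(object), seq_along(object)))
            msg <- c(msg, "bins must be sorted by (chromosome, start)")
        byChrom <- split(IRanges::ranges(object),
                         GenomicRanges::seqnames(object))
        overlapping <- vapply(byChrom, function(r)
            length(IRanges::reduce(r, min.gapwidth = 0L)) != length(r),
            logical(1))
        if (any(overlapping))
            msg <- c(msg, "bins overlap within a chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Per-sample copy-number profile over a bin grid
#'
#' Container for one embryo biopsy's read-depth profile: raw and
#' normalized per-bin counts, per-bin copy number (autosomal median
#' anchored at 2), the sliding-median smoothed track, per-chromosome
#' calls, and the sample-level ploidy verdict.
#'
#' @slot embryoId sample identifier.
#' @slot grid the [BinGrid-class] the counts are keyed to.
#' @slot rawCounts,normalizedCounts,cn,smoothedCn numeric vectors, one
#'   value per bin.
#' @slot calls a \code{DataFrame} with one row per chromosome:
#'   \code{chromosome}, \code{nBins}, \code{medianCn}, \code{state}.
#' @slot verdict \code{"euploid"} or \code{"aneuploid"}.
#'
#' @seealso [callCopyNumber()], [chromosomeCalls()], [isAneuploid()]
#' @export
setClass("CopyNumberProfile",
    representation(
        embryoId = "character",
        grid = "BinGrid",
        rawCounts = "numeric",
        normalizedCounts = "numeric",
        cn = "numeric",
        smoothedCn = "numeric",
        calls = "DataFrame",
        verdict = "character"
    )
)

setValidity("CopyNumberProfile", function(object) {
    n <- length(object@grid)
    msg <- character()
    for (s in c("rawCounts", "normalizedCounts", "cn", "smoothedCn")) {
        v <- slot(object, s)
        if (length(v) && length(v) != n)
            msg <- c(msg, sprintf("'%s' length (%d) != number of bins (%d)",
                                  s, length(v), n))
    }
    if (length(object@cn) && any(object@cn < 0, na.rm = TRUE))
        msg <- c(msg, "copy numbers must be non-negative")
    if (length(object@verdict) &&
        !object@verdict %in% c("euploid", "aneuploid"))
        msg <- c(msg, "verdict must be 'euploid' or 'aneuploid'")
    if (length(msg)) msg else TRUE
})

#' Viability threshold for an mtDNA quantification assay
#'
#' Assay-specific cutoff above which an embryo is predicted non-viable.
#' A model is either \code{fixed} (cutoff supplied, e.g. the published
#' 0.003 for qPCR relative quantity or 0.07 for the NGS percent) or
#' \code{derived} from a training cohort as the smallest multiple of a
#' rounding grid strictly above the largest value observed among
#' implanting embryos, so that no training implanter exceeds it.
#'
#' @slot assay \code{"qpcr"} or \code{"ngs"}.
#' @slot cutoff positive threshold in assay units (2^-ddCt relative
#'   quantity for qPCR; percent of aligned bases for NGS).
#' @slot derivation \code{"fixed"} or \code{"derived"}.
#' @slot trainingMaxImplanter largest training-implanter value
#'   (\code{NA} for fixed models).
#'
#' @seealso [deriveThreshold()], [fixedThreshold()], [classifyViability()]
#' @export
setClass("ThresholdModel",
    representation(
        assay = "character",
        cutoff = "numeric",
        derivation = "character",
        trainingMaxImplanter = "numeric"
    )
)

setValidity("ThresholdModel", function(object) {
    msg <- character()
    if (!object@assay %in% c("qpcr", "ngs"))
        msg <- c(msg, "assay must be 'qpcr' or 'ngs'")
    if (!object@derivation %in% c("fixed", "derived"))
        msg <- c(msg, "derivation must be 'fixed' or 'derived'")
    if (!is.finite(object@cutoff) || object@cutoff <= 0)
        msg <- c(msg, "cutoff must be a positive number")
    if (identical(object@derivation, "derived") &&
        (!is.finite(object@trainingMaxImplanter) ||
         object@cutoff <= object@trainingMaxImplanter))
        msg <- c(msg,
            "derived cutoff must exceed the training implanter maximum")
    if (length(msg)) msg else TRUE
})

#' Predictive-performance metrics of a viability threshold on a cohort
#'
#' Counts and rates from applying a [ThresholdModel-class] to embryos
#' with known transfer outcome. The negative predictive value (NPV) is
#' the share of above-cutoff embryos that indeed failed to implant;
#' \code{rateBelow} and \code{rateOverall} are implantation rates among
#' below-cutoff embryos and the whole cohort;
#' \code{flaggedNonimplanterFraction} is the share of non-implanters
#' that sit above the cutoff. All rates are percentages.
#'
#' @seealso [evaluateCohort()], [blindedValidate()], [npv()]
#' @export
setClass("CohortMetrics",
    representation(
        nTransferred = "numeric",
        nImplanted = "numeric",
        nAbove = "numeric",
        nAboveImplanted = "numeric",
        npv = "numeric",
        rateBelow = "numeric",
        rateOverall = "numeric",
        flaggedNonimplanterFraction = "numeric"
    )
)

setValidity("CohortMetrics", function(object) {
    msg <- character()
    if (object@nAboveImplanted > object@nAbove)
        msg <- c(msg, "nAboveImplanted cannot exceed nAbove")
    pct <- c(object@npv, object@rateBelow, object@rateOverall,
             object@flaggedNonimplanterFraction)
    pct <- pct[is.finite(pct)]
    if (any(pct < 0 | pct > 100))
        msg <- c(msg, "percent metrics must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' Synthetic-cohort generator settings
#'
#' Parameters of the synthetic trophectoderm-biopsy cohort generator.
#' Defaults encode the study conditions the downstream analyses assume:
#' an age mix over 26-42 years and per-age aneuploidy rates matching the
#' published per-age cohort composition, a latent log-normal relative
#' mtDNA quantity rising ~10%/year of maternal age at the blastocyst
#' stage (falling at cleavage stage), a 1.8-fold elevation in aneuploids,
#' a viability cutoff of 0.003 that implanting embryos never exceed, and
#' 30% of euploid non-implanters resampled above the cutoff. See the
#' package vignette for the rationale behind each default.
#'
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
    representation(
        nEmbryos = "numeric",
        ageWeights = "numeric",
        aneuploidyRateByAge = "numeric",
        cleavageFraction = "numeric",
        blastocystAgeEffect = "numeric",
        cleavageAgeEffect = "numeric",
        aneuploidyEffect = "numeric",
        implantationRate = "numeric",
        nonimplanterElevatedFraction = "numeric",
        viabilityCutoff = "numeric",
        rqBaseline = "numeric",
        cleavageRqBaseline = "numeric",
        referenceAge = "numeric",
        rqLognormalSigma = "numeric",
        ctNoiseSd = "numeric",
        aluCtBaseline = "numeric",
        nbDispersion = "numeric",
        gcBiasCoefficients = "numeric",
        meanReadsPerBin = "numeric",
        errorRate = "numeric",
        seed = "numeric"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@nEmbryos) != 1L || object@nEmbryos < 1)
        msg <- c(msg, "nEmbryos must be a positive count")
    if (!length(object@ageWeights) || all(object@ageWeights == 0))
        msg <- c(msg, "ageWeights must be non-empty with positive mass")
    if (is.null(names(object@ageWeights)))
        msg <- c(msg, "ageWeights must be named by age in years")
    probs <- c(object@aneuploidyRateByAge, object@cleavageFraction,
               object@implantationRate, object@nonimplanterElevatedFraction,
               object@errorRate)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    mult <- c(object@blastocystAgeEffect, object@cleavageAgeEffect,
              object@aneuploidyEffect)
    if (any(mult <= 0))
        msg <- c(msg, "multiplicative effects must be positive")
    pos <- c(object@viabilityCutoff, object@rqBaseline,
             object@cleavageRqBaseline, object@rqLognormalSigma,
             object@meanReadsPerBin)
    if (any(pos <= 0))
        msg <- c(msg, paste("viabilityCutoff, baselines, rqLognormalSigma",
                            "and meanReadsPerBin must be positive"))
    if (object@ctNoiseSd < 0 || object@nbDispersion < 0)
        msg <- c(msg, "ctNoiseSd and nbDispersion must be non-negative")
    if (length(object@gcBiasCoefficients) != 3L)
        msg <- c(msg, "gcBiasCoefficients must have length 3")
    if (length(msg)) msg else TRUE
})
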