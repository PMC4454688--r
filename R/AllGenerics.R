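#' @include AllClasses.R
NULL

#' Accessors for bin-grid metadata
#'
#' `binGC()` returns the per-bin GC fraction, `referenceWeights()` the
#' in-silico reference weights and `mappable36mers()` the per-bin count
#' of uniquely mapping 36-mers of a [BinGrid-class].
#'
#' @param x a `BinGrid`.
#' @return a numeric (or integer) vector with one value per bin.
#' @examples
#' g <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 5, seed = 1)
#' binGC(g)
#' @export
setGeneric("binGC", function(x) standardGeneric("binGC"))

#' @rdname binGC
#' @export
setGeneric("referenceWeights",
           function(x) standardGeneric("referenceWeights"))

#' @rdname binGC
#' @export
setGeneric("mappable36mers",
           function(x) standardGeneric("mappable36mers"))

#' @rdname binGC
setMethod("binGC", "BinGrid", function(x) mcols(x)$gc)

#' @rdname binGC
setMethod("referenceWeights", "BinGrid",
          function(x) mcols(x)$referenceWeight)

#' @rdname binGC
setMethod("mappable36mers", "BinGrid",
          function(x) mcols(x)$mappable36mers)

#' Accessors for copy-number profiles
#'
#' Extract the per-bin tracks, per-chromosome calls and ploidy verdict
#' from a [CopyNumberProfile-class].
#'
#' @param x a `CopyNumberProfile`.
#' @return `rawCounts()`, `normalizedCounts()`, `cnPerBin()` and
#'   `smoothedCn()` return one numeric value per bin;
#'   `chromosomeCalls()` a `DataFrame` with one row per chromosome
#'   (`chromosome`, `nBins`, `medianCn`, `state`); `isAneuploid()` a
#'   logical scalar; `embryoId()` the sample identifier.
#' @seealso [callCopyNumber()]
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname rawCounts
#' @export
setGeneric("normalizedCounts",
           function(x) standardGeneric("normalizedCounts"))

#' @rdname rawCounts
#' @export
setGeneric("cnPerBin", function(x) standardGeneric("cnPerBin"))

#' @rdname rawCounts
#' @export
setGeneric("smoothedCn", function(x) standardGeneric("smoothedCn"))

#' @rdname rawCounts
#' @export
setGeneric("chromosomeCalls",
           function(x) standardGeneric("chromosomeCalls"))

#' @rdname rawCounts
#' @export
setGeneric("isAneuploid", function(x) standardGeneric("isAneuploid"))

#' @rdname rawCounts
#' @export
setGeneric("embryoId", function(x) standardGeneric("embryoId"))

#' @rdname rawCounts
setMethod("rawCounts", "CopyNumberProfile", function(x) x@rawCounts)

#' @rdname rawCounts
setMethod("normalizedCounts", "CopyNumberProfile",
          function(x) x@normalizedCounts)

#' @rdname rawCounts
setMethod("cnPerBin", "CopyNumberProfile", function(x) x@cn)

#' @rdname rawCounts
setMethod("smoothedCn", "CopyNumberProfile", function(x) x@smoothedCn)

#' @rdname rawCounts
setMethod("chromosomeCalls", "CopyNumberProfile", function(x) x@calls)

#' @rdname rawCounts
setMethod("isAneuploid", "CopyNumberProfile",
          function(x) identical(x@verdict, "aneuploid"))

#' @rdname rawCounts
setMethod("embryoId", "CopyNumberProfile", function(x) x@embryoId)

#' Accessors for threshold models and cohort metrics
#'
#' `cutoff()` returns a [ThresholdModel-class]'s viability cutoff in
#' assay units and `assay()` its assay label. `npv()` returns the
#' negative predictive value (percent) stored in a
#' [CohortMetrics-class], `NA` when no embryo exceeded the cutoff.
#'
#' @param x a `ThresholdModel` or `CohortMetrics`.
#' @export
setGeneric("cutoff", function(x) standardGeneric("cutoff"))

#' @rdname cutoff
#' @export
setGeneric("assayName", function(x) standardGeneric("assayName"))

#' @rdname cutoff
#' @export
setGeneric("npv", function(x) standardGeneric("npv"))

#' @rdname cutoff
setMethod("cutoff", "ThresholdModel", function(x) x@cutoff)

#' @rdname cutoff
setMethod("assayName", "ThresholdModel", function(x) x@assay)

#' @rdname cutoff
setMethod("npv", "CohortMetrics", function(x) x@npv)

setMethod("show", "BinGrid", function(object) {
    cat(sprintf("BinGrid with %d bins on %d chromosome(s)\n",
                length(object),
                length(GenomeInfoDb::seqlevelsInUse(object))))
    callNextMethod()
})

setMethod("show", "CopyNumberProfile", function(object) {
    cat(sprintf("CopyNumberProfile for '%s': %d bins, %d chromosome(s)\n",
                object@embryoId, length(object@grid),
                nrow(object@calls)))
    if (length(object@verdict)) {
        nonNeutral <- object@calls[!is.na(object@calls$state) &
                                   object@calls$state != "neutral", ,
                                   drop = FALSE]
        cat(sprintf("verdict: %s", object@verdict))
        if (nrow(nonNeutral))
            cat(sprintf(" (%s)", paste(nonNeutral$chromosome,
                                       nonNeutral$state, collapse = ", ")))
        cat("\n")
    }
    invisible(NULL)
})

setMethod("show", "ThresholdModel", function(object) {
    cat(sprintf("ThresholdModel (%s): cutoff %g [%s]\n", object@assay,
                object@cutoff, object@derivation))
    if (is.finite(object@trainingMaxImplanter))
        cat(sprintf("  training implanter maximum: %g\n",
                    object@trainingMaxImplanter))
    invisible(NULL)
})

setMethod("show", "CohortMetrics", function(object) {
    cat("CohortMetrics\n")
    cat(sprintf("  transferred: %d, implanted: %d (%.1f%% overall)\n",
                object@nTransferred, object@nImplanted,
                object@rateOverall))
    cat(sprintf("  above cutoff: %d (implanted: %d), NPV: %s\n",
                object@nAbove, object@nAboveImplanted,
                if (is.finite(object@npv))
                    sprintf("%.1f%%", object@npv) else "n/a"))
    cat(sprintf("  implantation below cutoff: %s\n",
                if (is.finite(object@rateBelow))
                    sprintf("%.1f%%", object@rateBelow) else "n/a"))
    cat(sprintf("  non-implanters above cutoff: %.1f%%\n",
                object@flaggedNonimplanterFraction))
    invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0(
        "SimulationConfig: %d embryos, ages %s-%s, cutoff %g\n",
        "  age effect %.2fx/yr (blastocyst), %.2fx/yr (cleavage), ",
        "aneuploidy %.2fx\n"),
        object@nEmbryos, min(names(object@ageWeights)),
        max(names(object@ageWeights)), object@viabilityCutoff,
        object@blastocystAgeEffect, object@cleavageAgeEffect,
        object@aneuploidyEffect))
    invisible(NULL)
})
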