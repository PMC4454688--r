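#' @include utils.R
NULL

#' Mitochondrial fraction of aligned sequencing bases
#'
#' The NGS analogue of the qPCR relative quantity: the share of aligned
#' bases attributable to the mitochondrial genome,
#' `100 * mito / (mito + nuclear)`, reported in percent of the total.
#' The nuclear genome dominates the denominator and acts as the control
#' for the number of cells in the biopsy. The value is scale-invariant:
#' multiplying both base counts by any positive constant leaves it
#' unchanged.
#'
#' @param mitoBases,nuclearBases non-negative aligned base counts
#'   (vectorized; pairwise totals must be positive).
#' @param threshold classification cutoff in percent (default 0.07, the
#'   published NGS viability threshold).
#' @param embryoId optional sample identifiers.
#' @return a `data.frame` with `embryo_id` (if given), `mito_bases`,
#'   `nuclear_bases`, `fraction_percent` and `class`.
#' @examples
#' mitoFraction(3200, 996800)$fraction_percent  # 0.32
#' @export
mitoFraction <- function(mitoBases, nuclearBases, threshold = 0.07,
                         embryoId = NULL) {
    if (any(mitoBases < 0 | nuclearBases < 0))
        stop("base counts must be non-negative")
    total <- mitoBases + nuclearBases
    if (any(total <= 0))
        stop("total aligned bases must be positive")
    pct <- 100 * mitoBases / total
    out <- data.frame(mito_bases = mitoBases,
                      nuclear_bases = nuclearBases,
                      fraction_percent = pct,
                      class = classifyNgs(pct, threshold),
                      stringsAsFactors = FALSE)
    if (!is.null(embryoId)) out <- cbind(embryo_id = embryoId, out)
    out
}

#' Classify an NGS mitochondrial percent against the viability threshold
#'
#' `"high_abnormal"` when the percent strictly exceeds the threshold,
#' else `"low_normal"`; a value exactly at the cutoff is low/normal,
#' mirroring [classifyQpcr()].
#'
#' @param fractionPercent mitochondrial fractions in percent,
#'   in `[0, 100]`.
#' @param threshold cutoff in percent (default 0.07).
#' @return character vector in `{"low_normal", "high_abnormal"}`.
#' @examples
#' classifyNgs(c(0.06, 0.08, 0.07))
#' @export
classifyNgs <- function(fractionPercent, threshold = 0.07) {
    if (any(!is.finite(fractionPercent) | fractionPercent < 0 |
            fractionPercent > 100))
        stop("fractions must lie in [0, 100] percent")
    .assertScalarNumber(threshold, "threshold", positive = TRUE)
    ifelse(fractionPercent > threshold, "high_abnormal", "low_normal")
}

#' Call heteroplasmic sites from a mitochondrial pileup
#'
#' Reports sites with adequate depth whose alternate-allele fraction
#' indicates heteroplasmy: with `f = alt / (ref + alt)`, a site of
#' depth at least `minDepth` is `heteroplasmic` when
#' `minFraction <= f <= 1 - minFraction` and `homoplasmic_alt` when
#' `f > 1 - minFraction`. Homoplasmic-reference sites are not listed.
#' Sites below `minDepth` yield no call regardless of fraction.
#'
#' @param pileup `data.frame` with `position` (1-based, within the
#'   16,569 bp mitochondrial genome), `ref_count` and `alt_count`.
#' @param minDepth minimum read depth for any call (default 20).
#' @param minFraction minor-allele fraction defining heteroplasmy
#'   (default 0.05).
#' @return a `data.frame` (`position`, `depth`, `fraction`, `status`),
#'   one row per called site.
#' @examples
#' p <- data.frame(position = 1:3, ref_count = c(75, 5, 0),
#'                 alt_count = c(75, 5, 150))
#' heteroplasmyCalls(p)
#' @export
heteroplasmyCalls <- function(pileup, minDepth = 20L, minFraction = 0.05) {
    need <- c("position", "ref_count", "alt_count")
    missing <- setdiff(need, names(pileup))
    if (length(missing))
        stop("pileup lacks column(s): ", paste(missing, collapse = ", "))
    if (minFraction <= 0 || minFraction >= 0.5)
        stop("'minFraction' must lie in (0, 0.5)")
    if (any(pileup$position < 1L | pileup$position > 16569L))
        stop("positions must lie within the 16,569 bp mitochondrial genome")
    if (any(pileup$ref_count < 0 | pileup$alt_count < 0))
        stop("pileup counts must be non-negative")
    depth <- pileup$ref_count + pileup$alt_count
    ok <- depth >= minDepth & depth > 0
    frac <- ifelse(ok, pileup$alt_count / depth, NA_real_)
    status <- rep(NA_character_, nrow(pileup))
    status[ok & frac >= minFraction & frac <= 1 - minFraction] <-
        "heteroplasmic"
    status[ok & frac > 1 - minFraction] <- "homoplasmic_alt"
    keep <- !is.na(status)
    data.frame(position = pileup$position[keep], depth = depth[keep],
               fraction = frac[keep], status = status[keep],
               stringsAsFactors = FALSE)
}

#' Compare mutation load between high- and low-mtDNA groups
#'
#' Counts heteroplasmic sites per sample in each group and compares the
#' two groups with a two-tailed test - the question being whether
#' samples with elevated mtDNA carry more heteroplasmic mutations than
#' samples with normal levels.
#'
#' @param groupHigh,groupLow lists of per-sample heteroplasmy-call
#'   tables (as returned by [heteroplasmyCalls()]), or numeric vectors
#'   of per-sample heteroplasmic-site counts.
#' @param method `"welch"` (default, via [tTestUnpaired()]) or
#'   `"wilcoxon"` (rank-based, via [stats::wilcox.test()]).
#' @return a list: `countsHigh`, `countsLow`, `meanHigh`, `meanLow`,
#'   `pTwoTailed`, `method`. When either group has fewer than 2
#'   samples the comparison is skipped with a warning (`pTwoTailed`
#'   is `NA`).
#' @export
mutationLoadCompare <- function(groupHigh, groupLow,
                                method = c("welch", "wilcoxon")) {
    method <- match.arg(method)
    perSample <- function(g) {
        if (is.numeric(g)) return(as.numeric(g))
        if (!length(g)) return(numeric(0))
        vapply(g, function(calls)
            sum(calls$status == "heteroplasmic"), numeric(1))
    }
    high <- perSample(groupHigh)
    low <- perSample(groupLow)
    if (!length(high) || !length(low))
        stop("both groups must be non-empty")
    p <- NA_real_
    if (length(high) < 2L || length(low) < 2L) {
        warning("group with fewer than 2 samples: comparison skipped")
    } else if (method == "welch") {
        p <- tTestUnpaired(high, low, variant = "welch")$pTwoTailed
    } else {
        p <- suppressWarnings(
            wilcox.test(high, low, exact = FALSE)$p.value)
    }
    list(countsHigh = high, countsLow = low,
         meanHigh = mean(high), meanLow = mean(low),
         pTwoTailed = p, method = method)
}
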