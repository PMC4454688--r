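#' @include AllClasses.R utils.R
NULL

#' Filter alignment records for copy-number analysis
#'
#' Keeps reads that are mapped, non-duplicate, have a mapping score of
#' at least `minMappingScore` and at most `maxMismatches` mismatches
#' with the reference (the shallow-sequencing convention removes reads
#' with more than one mismatch). An empty result is allowed.
#'
#' @param records `data.frame` with logical columns `mapped` and
#'   `duplicate`, and numeric `mapping_score` and `mismatches`, plus
#'   whatever positional columns the caller carries along.
#' @param minMappingScore minimum mapping score kept (no universal
#'   default exists for "low mapping scores"; callers choose, e.g. 30).
#' @param maxMismatches maximum mismatch count kept (default 1).
#' @return the kept rows of `records`.
#' @examples
#' reads <- data.frame(mapped = TRUE, duplicate = FALSE,
#'                     mapping_score = 60, mismatches = c(0, 2),
#'                     chrom = "chr1", pos = c(10, 20))
#' filterAlignments(reads, minMappingScore = 30)
#' @export
filterAlignments <- function(records, minMappingScore, maxMismatches = 1L) {
    need <- c("mapped", "duplicate", "mapping_score", "mismatches")
    missing <- setdiff(need, names(records))
    if (length(missing))
        stop("alignment table lacks column(s): ",
             paste(missing, collapse = ", "))
    keep <- records$mapped & !records$duplicate &
        records$mapping_score >= minMappingScore &
        records$mismatches <= maxMismatches
    records[keep, , drop = FALSE]
}

#' Read an alignment summary from a SAM/BAM file
#'
#' Maps alignment records to the columns [filterAlignments()] expects:
#' the mapped and duplicate flags, the mapping quality, the `NM` tag as
#' the mismatch count (reads without an `NM` tag get 0), the reference
#' name and the 0-based leftmost position. Requires the `Rsamtools`
#' package.
#'
#' @param file path to a SAM or BAM file.
#' @return a `data.frame` with columns `mapped`, `duplicate`,
#'   `mapping_score`, `mismatches`, `chrom`, `pos`.
#' @export
readAlignmentSummary <- function(file) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
        stop("reading SAM/BAM requires the 'Rsamtools' package")
    if (grepl("\\.sam$", file, ignore.case = TRUE))
        file <- Rsamtools::asBam(file,
                                 destination = tempfile(fileext = ""),
                                 overwrite = TRUE, indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
        what = c("flag", "rname", "pos", "mapq"), tag = "NM")
    b <- Rsamtools::scanBam(file, param = p)[[1L]]
    flag <- b$flag
    nm <- b$tag$NM
    if (is.null(nm)) nm <- rep(0L, length(flag))
    nm[is.na(nm)] <- 0L
    data.frame(
        mapped = bitwAnd(flag, 4L) == 0L,
        duplicate = bitwAnd(flag, 1024L) > 0L,
        mapping_score = ifelse(is.na(b$mapq), 0L, b$mapq),
        mismatches = nm,
        chrom = as.character(b$rname),
        pos = ifelse(is.na(b$pos), NA_integer_, b$pos - 1L),
        stringsAsFactors = FALSE)
}

#' Count reads per bin
#'
#' Assigns each read to the bin whose 0-based half-open interval
#' contains its start position. Reads landing outside every bin (or on
#' chromosomes absent from the grid) are dropped and tallied in a
#' message, never an error.
#'
#' @param records filtered alignment `data.frame` with columns `chrom`
#'   and `pos` (0-based read start).
#' @param grid a [BinGrid-class].
#' @return integer vector of read counts, one per bin.
#' @examples
#' g <- binGrid("chr1", start = c(0, 100), end = c(100, 200),
#'              gc = c(0.4, 0.5))
#' reads <- data.frame(chrom = "chr1", pos = c(0, 99, 100, 250))
#' countReadsPerBin(reads, g)  # bin boundaries are half-open
#' @export
countReadsPerBin <- function(records, grid) {
    stopifnot(is(grid, "BinGrid"))
    if (length(grid) == 0L) stop("bin grid is empty")
    if (!all(c("chrom", "pos") %in% names(records)))
        stop("alignment table lacks 'chrom'/'pos' columns")
    counts <- integer(length(grid))
    if (nrow(records) == 0L) return(counts)
    onGrid <- records$chrom %in% seqlevels(grid) & !is.na(records$pos)
    dropped <- sum(!onGrid)
    if (any(onGrid)) {
        reads <- GRanges(records$chrom[onGrid],
                         IRanges(start = records$pos[onGrid] + 1L,
                                 width = 1L))
        hits <- findOverlaps(reads, grid)
        counts <- S4Vectors::countSubjectHits(hits)
        dropped <- dropped + sum(S4Vectors::countQueryHits(hits) == 0L)
    }
    if (dropped > 0L)
        message(sprintf("countReadsPerBin: dropped %d read(s) outside ",
                        dropped), "the bin grid")
    counts
}

# Merge 1%-GC strata until each merged stratum holds >= minBins bins.
.gcStrata <- function(gc, minBins) {
    stratum <- as.integer(floor(pmin(gc, 0.999999) * 100))
    lev <- sort(unique(stratum))
    sizes <- tabulate(match(stratum, lev), nbins = length(lev))
    group <- integer(length(lev))
    g <- 1L; acc <- 0L
    for (i in seq_along(lev)) {
        group[i] <- g
        acc <- acc + sizes[i]
        if (acc >= minBins && i < length(lev)) { g <- g + 1L; acc <- 0L }
    }
    # fold a trailing undersized group into its neighbour
    if (acc < minBins && g > 1L) group[group == g] <- g - 1L
    group[match(stratum, lev)]
}

#' GC and in-silico reference normalization of bin counts
#'
#' Removes coverage bias in two deterministic steps: counts are divided
#' by the median count of their GC stratum (GC binned in 1% strata;
#' undersized strata are merged with neighbours until each holds at
#' least `minBinsPerStratum` bins) relative to the global median count,
#' then divided by the bin's in-silico `referenceWeight`. The
#' stratified median is robust and standard for shallow
#' whole-genome-sequencing copy-number work.
#'
#' @param counts raw per-bin read counts (one per bin of `grid`).
#' @param grid a [BinGrid-class].
#' @param minBinsPerStratum minimum bins per GC stratum before
#'   neighbouring strata are merged (default 20).
#' @return numeric vector of normalized counts, one per bin.
#' @examples
#' g <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 100,
#'                       seed = 1)
#' x <- simulateBinCounts(g, simulationConfig(seed = 1))
#' norm <- gcNormalize(x, g)
#' @export
gcNormalize <- function(counts, grid, minBinsPerStratum = 20L) {
    stopifnot(is(grid, "BinGrid"))
    if (length(counts) != length(grid))
        stop("'counts' length must match the number of bins")
    if (all(counts == 0))
        stop("all bin counts are zero: sample failed")
    globalMed <- median(counts)
    group <- .gcStrata(binGC(grid), minBinsPerStratum)
    stratMed <- vapply(split(counts, group), median, numeric(1))
    ratio <- unname(stratMed[as.character(group)]) / globalMed
    ratio[!is.finite(ratio) | ratio <= 0] <- 1
    as.numeric(counts) / ratio / referenceWeights(grid)
}

#' Per-bin copy number
#'
#' Converts normalized counts to copy numbers by anchoring the median
#' autosomal count at two copies:
#' `cn_i = normalized_i / median(autosomal normalized) * 2`. Sex
#' chromosomes are excluded from the normalizing median but still
#' receive copy-number values. Zero-count bins keep copy number 0 - no
#' masking.
#'
#' @param normalizedCounts normalized per-bin counts (one per bin).
#' @param grid a [BinGrid-class].
#' @return numeric copy numbers, one per bin; the median over autosomal
#'   bins is exactly 2 by construction.
#' @export
copyNumberPerBin <- function(normalizedCounts, grid) {
    stopifnot(is(grid, "BinGrid"))
    if (length(normalizedCounts) != length(grid))
        stop("'normalizedCounts' length must match the number of bins")
    auto <- .isAutosome(seqnames(grid))
    if (!any(auto)) stop("grid contains no autosomal bins")
    med <- median(normalizedCounts[auto])
    if (!is.finite(med) || med <= 0)
        stop("autosomal median count is zero: cannot scale to copy number")
    normalizedCounts / med * 2
}

# Sliding median with symmetric window shrinkage at the edges: the
# window at position i spans i - h .. i + h with
# h = min((k-1)/2, i-1, n-i), so no position is discarded.
.slidingMedian <- function(x, k) {
    n <- length(x)
    if (n == 0L) return(x)
    h <- (k - 1L) %/% 2L
    out <- if (n >= k && k >= 3L)
        stats::runmed(x, k, endrule = "keep")
    else x
    edge <- seq_len(min(h, n))
    for (i in unique(c(edge, n - edge + 1L))) {
        hh <- min(h, i - 1L, n - i)
        out[i] <- median(x[(i - hh):(i + hh)])
    }
    out
}

#' Sliding-median smoothing of a copy-number track
#'
#' Smooths per-bin copy numbers with a sliding median (default window
#' 13 bins) computed independently within each chromosome - smoothing
#' never crosses a chromosome boundary. At chromosome edges the window
#' shrinks symmetrically to the available bins, so edge bins are
#' retained rather than discarded.
#'
#' @param cn per-bin copy numbers (one per bin of `grid`).
#' @param grid a [BinGrid-class].
#' @param window odd window size in bins (default 13).
#' @return smoothed copy numbers, one per bin.
#' @examples
#' g <- syntheticBinGrid(chromosomes = "chr1", binsPerChromosome = 30,
#'                       seed = 1)
#' cn <- rep(2, 30); cn[15] <- 10    # single outlier bin
#' smoothCopyNumber(cn, g)[15]      # median rejects it
#' @export
smoothCopyNumber <- function(cn, grid, window = 13L) {
    stopifnot(is(grid, "BinGrid"))
    if (length(cn) != length(grid))
        stop("'cn' length must match the number of bins")
    window <- as.integer(window)
    if (window < 1L || window %% 2L == 0L)
        stop("'window' must be an odd positive integer")
    chrom <- as.character(seqnames(grid))
    out <- numeric(length(cn))
    for (chr in unique(chrom)) {
        idx <- which(chrom == chr)
        out[idx] <- .slidingMedian(cn[idx], window)
    }
    out
}

#' Call per-chromosome copy-number states
#'
#' Each chromosome's status is the median of its smoothed per-bin copy
#' numbers: gain when the median is at or above `gainCutoff`, loss when
#' at or below `lossCutoff`, else neutral. The default cutoffs 2.5/1.5
#' are the midpoints between integer copy states. Sex chromosomes are
#' assessed against the copy number expected for a declared `sex`
#' (shifting the cutoffs by the expected-minus-two difference); without
#' a declared sex their medians are reported with state `NA` and do not
#' enter the verdict. The sample verdict is aneuploid when any assessed
#' chromosome is non-neutral.
#'
#' @param smoothedCn smoothed per-bin copy numbers (one per bin).
#' @param grid a [BinGrid-class].
#' @param gainCutoff,lossCutoff chromosome-median cutoffs (defaults
#'   2.5 and 1.5).
#' @param sex `"male"`, `"female"` or `NA` (default).
#' @return a list with `calls` (a `DataFrame`: `chromosome`, `nBins`,
#'   `medianCn`, `state`) and `verdict` (`"euploid"`/`"aneuploid"`).
#' @export
callChromosomes <- function(smoothedCn, grid, gainCutoff = 2.5,
                            lossCutoff = 1.5, sex = NA_character_) {
    stopifnot(is(grid, "BinGrid"))
    if (length(smoothedCn) != length(grid))
        stop("'smoothedCn' length must match the number of bins")
    if (gainCutoff <= lossCutoff)
        stop("'gainCutoff' must exceed 'lossCutoff'")
    chrom <- as.character(seqnames(grid))
    lev <- unique(chrom)
    med <- vapply(lev, function(chr) median(smoothedCn[chrom == chr]),
                  numeric(1))
    nBins <- vapply(lev, function(chr) sum(chrom == chr), integer(1))
    expected <- vapply(lev, function(chr) {
        if (.isAutosome(chr)) return(2)
        if (is.na(sex)) return(NA_real_)
        isX <- chr %in% c("chrX", "X")
        if (identical(sex, "male")) 1
        else if (isX) 2 else 0
    }, numeric(1))
    state <- rep(NA_character_, length(lev))
    assessed <- !is.na(expected)
    shift <- expected[assessed] - 2
    state[assessed] <- ifelse(
        med[assessed] >= gainCutoff + shift, "gain",
        ifelse(med[assessed] <= lossCutoff + shift, "loss", "neutral"))
    calls <- DataFrame(chromosome = lev, nBins = nBins, medianCn = med,
                       state = state)
    verdict <- if (any(state[assessed] != "neutral")) "aneuploid"
               else "euploid"
    list(calls = calls, verdict = verdict)
}

#' Run the full read-depth copy-number pipeline for one sample
#'
#' Convenience wrapper chaining [gcNormalize()], [copyNumberPerBin()],
#' [smoothCopyNumber()] and [callChromosomes()] into a
#' [CopyNumberProfile-class].
#'
#' @param counts raw per-bin read counts.
#' @param grid a [BinGrid-class].
#' @param embryoId sample identifier.
#' @param window sliding-median window (odd; default 13 bins).
#' @param gainCutoff,lossCutoff chromosome-call cutoffs.
#' @param sex optional declared sample sex for X/Y assessment.
#' @param normalize set `FALSE` to skip GC/reference normalization
#'   (counts are then used as already-normalized values).
#' @param minBinsPerStratum passed to [gcNormalize()].
#' @return a [CopyNumberProfile-class].
#' @examples
#' g <- syntheticBinGrid(chromosomes = paste0("chr", 1:4),
#'                       binsPerChromosome = 30, seed = 1)
#' cfg <- simulationConfig(seed = 2)
#' x <- simulateBinCounts(g, cfg, aneuploidChromosomes = c(chr3 = 3))
#' prof <- callCopyNumber(x, g, embryoId = "E1")
#' chromosomeCalls(prof)
#' @export
callCopyNumber <- function(counts, grid, embryoId = "sample",
                           window = 13L, gainCutoff = 2.5,
                           lossCutoff = 1.5, sex = NA_character_,
                           normalize = TRUE, minBinsPerStratum = 20L) {
    norm <- if (normalize)
        gcNormalize(counts, grid, minBinsPerStratum) else as.numeric(counts)
    cn <- copyNumberPerBin(norm, grid)
    sm <- smoothCopyNumber(cn, grid, window)
    ch <- callChromosomes(sm, grid, gainCutoff, lossCutoff, sex)
    new("CopyNumberProfile", embryoId = embryoId, grid = grid,
        rawCounts = as.numeric(counts), normalizedCounts = norm,
        cn = cn, smoothedCn = sm, calls = ch$calls,
        verdict = ch$verdict)
}
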