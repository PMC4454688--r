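#' @include AllClasses.R utils.R
NULL

#' Construct a bin grid
#'
#' Builds a [BinGrid-class] from per-bin vectors. Coordinates are
#' supplied in the BED convention (0-based half-open), matching the
#' on-disk grid format, and stored internally as 1-based closed ranges.
#'
#' @param chrom chromosome label per bin.
#' @param start,end 0-based half-open bin coordinates.
#' @param gc GC fraction per bin, in `[0, 1]`.
#' @param mappable36mers number of uniquely mapping 36-mers per bin
#'   (100 for canonical grids).
#' @param referenceWeight positive in-silico reference weight per bin
#'   (expected relative coverage in a normal reference data set).
#' @return a validated [BinGrid-class].
#' @examples
#' binGrid(chrom = c("chr1", "chr1"), start = c(0, 100), end = c(100, 200),
#'         gc = c(0.4, 0.5))
#' @export
binGrid <- function(chrom, start, end, gc, mappable36mers = 100L,
                    referenceWeight = 1) {
    chrom <- rep_len(chrom, length(start))
    stopifnot(length(start) == length(end), length(gc) == length(start))
    if (any(end <= start))
        stop("bin end must exceed bin start (0-based half-open)")
    gr <- GRanges(chrom, IRanges(start = start + 1L, end = end))
    mcols(gr)$gc <- as.numeric(gc)
    mcols(gr)$mappable36mers <- rep_len(as.integer(mappable36mers),
                                        length(gr))
    mcols(gr)$referenceWeight <- rep_len(as.numeric(referenceWeight),
                                         length(gr))
    ord <- BiocGenerics::order(gr)
    new("BinGrid", gr[ord])
}

#' Build a synthetic fixed-width bin grid
#'
#' Real grids have variable genomic width and a fixed mappability
#' content (100 uniquely mapping 36-mers per bin); mappability tracks
#' are outside this package's scope, so the synthetic builder uses
#' fixed-width bins and records `mappable36mers = 100`. GC fractions
#' are drawn uniformly from `gcRange`, reference weights default to 1.
#'
#' @param chromosomes chromosome labels (default the 22 autosomes).
#' @param binsPerChromosome bins per chromosome (scalar or one value
#'   per chromosome).
#' @param binWidth bin width in bases.
#' @param gcRange range GC fractions are drawn from.
#' @param seed optional integer seed for the GC draw.
#' @return a [BinGrid-class].
#' @examples
#' syntheticBinGrid(chromosomes = c("chr1", "chr2"),
#'                  binsPerChromosome = 20, seed = 1)
#' @export
syntheticBinGrid <- function(chromosomes = paste0("chr", 1:22),
                             binsPerChromosome = 40L,
                             binWidth = 100000L,
                             gcRange = c(0.3, 0.6),
                             seed = NA_integer_) {
    nBins <- rep_len(as.integer(binsPerChromosome), length(chromosomes))
    chrom <- rep(chromosomes, nBins)
    start <- unlist(lapply(nBins, function(k)
        (seq_len(k) - 1L) * as.integer(binWidth)), use.names = FALSE)
    if (!is.na(seed)) set.seed(.substreamSeed(seed, "bingrid"))
    gc <- runif(length(chrom), gcRange[1L], gcRange[2L])
    binGrid(chrom, start, start + as.integer(binWidth), gc)
}
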