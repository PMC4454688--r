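#' @import methods
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevelsInUse
#' @importFrom stats median rnorm rpois rbinom rnbinom runif qnorm pnorm
#'   sd t.test wilcox.test var
#' @importFrom utils read.csv write.csv read.delim write.table packageVersion
NULL

# Deterministic substream seeds: one global seed, one substream per
# operation (and optionally per record), all below 2^31.
.substreamSeed <- function(seed, op, index = 0L) {
    stopifnot(length(seed) == 1L, is.finite(seed))
    codes <- utf8ToInt(op)
    opcode <- sum(codes * seq_along(codes))
    as.integer((abs(seed) %% 2147483647 * 48271 + opcode * 1009 +
                index * 7919) %% 2147483629)
}

.maybeSeed <- function(seed, op, index = 0L) {
    if (!is.null(seed) && length(seed) == 1L && is.finite(seed))
        set.seed(.substreamSeed(seed, op, index))
    invisible(NULL)
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name),
             call. = FALSE)
    if (positive && x <= 0)
        stop(sprintf("'%s' must be positive", name), call. = FALSE)
    invisible(x)
}

.sexChromosomes <- c("chrX", "chrY", "X", "Y")

.isAutosome <- function(chrom)
    !(as.character(chrom) %in% c(.sexChromosomes, "chrM", "MT", "M"))
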