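#' @include AllClasses.R utils.R grid.R
NULL

.sampleSheetColumns <- c("embryo_id", "maternal_age", "stage", "ploidy",
                         "outcome")

#' Load and validate a sample sheet
#'
#' Reads a cohort sample sheet CSV. The required columns are
#' `embryo_id`, `maternal_age`, `stage` (`cleavage`/`blastocyst`),
#' `ploidy` (`euploid`/`aneuploid`) and `outcome` (`implanted`/
#' `not_implanted`/`unknown`); unknown extra columns are preserved.
#' A duplicated embryo id or a missing required column is an error;
#' an age outside 18-50 only draws a warning.
#'
#' @param path path to a CSV file.
#' @return a validated `data.frame` of embryo records.
#' @export
loadSampleSheet <- function(path) {
    sheet <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                      error = function(e)
                          stop("cannot read sample sheet '", path, "': ",
                               conditionMessage(e), "; required columns: ",
                               paste(.sampleSheetColumns, collapse = ", "),
                               call. = FALSE))
    missing <- setdiff(.sampleSheetColumns, names(sheet))
    if (length(missing))
        stop("sample sheet lacks required column(s): ",
             paste(missing, collapse = ", "),
             " (required: ", paste(.sampleSheetColumns, collapse = ", "),
             ")")
    dup <- unique(sheet$embryo_id[duplicated(sheet$embryo_id)])
    if (length(dup))
        stop("duplicated embryo_id: ", paste(dup, collapse = ", "))
    badStage <- setdiff(unique(sheet$stage), c("cleavage", "blastocyst"))
    if (length(badStage))
        stop("unrecognized stage value(s): ",
             paste(badStage, collapse = ", "))
    badPloidy <- setdiff(unique(sheet$ploidy), c("euploid", "aneuploid"))
    if (length(badPloidy))
        stop("unrecognized ploidy value(s): ",
             paste(badPloidy, collapse = ", "))
    badOutcome <- setdiff(unique(sheet$outcome),
                          c("implanted", "not_implanted", "unknown"))
    if (length(badOutcome))
        stop("unrecognized outcome value(s): ",
             paste(badOutcome, collapse = ", "))
    offAge <- sheet$maternal_age < 18 | sheet$maternal_age > 50
    if (any(offAge))
        warning(sprintf("%d record(s) with maternal age outside 18-50",
                        sum(offAge)))
    sheet
}

#' @rdname loadSampleSheet
#' @param records cohort `data.frame` (extra columns are kept).
#' @export
writeSampleSheet <- function(records, path) {
    missing <- setdiff(.sampleSheetColumns, names(records))
    if (length(missing))
        stop("records lack required column(s): ",
             paste(missing, collapse = ", "))
    write.csv(records, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read and write qPCR Ct tables
#'
#' Long-format CSV with one row per (sample, assay) triplicate:
#' `embryo_id`, `assay` (`mt`/`alu`), `rep1`, `rep2`, `rep3`.
#'
#' @param path CSV file path.
#' @return `readCtTable()` returns the `data.frame`; `writeCtTable()`
#'   invisibly returns the path.
#' @export
readCtTable <- function(path) {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("embryo_id", "assay", "rep1", "rep2", "rep3")
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
    tab
}

#' @rdname readCtTable
#' @param ctTable Ct `data.frame` as produced by [simulateQpcrTable()].
#' @export
writeCtTable <- function(ctTable, path) {
    write.csv(ctTable, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read and write bin grids
#'
#' BED-like TSV with 0-based half-open coordinates and columns `chrom`,
#' `start`, `end`, `gc_fraction`, `mappable_36mers`, `reference_weight`.
#'
#' @param path TSV file path.
#' @return `readBinGrid()` returns a [BinGrid-class]; `writeBinGrid()`
#'   invisibly returns the path.
#' @export
readBinGrid <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "gc_fraction", "mappable_36mers",
              "reference_weight")
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop("bin grid lacks column(s): ", paste(missing, collapse = ", "))
    binGrid(tab$chrom, tab$start, tab$end, tab$gc_fraction,
            tab$mappable_36mers, tab$reference_weight)
}

#' @rdname readBinGrid
#' @param grid a [BinGrid-class].
#' @export
writeBinGrid <- function(grid, path) {
    stopifnot(is(grid, "BinGrid"))
    tab <- data.frame(chrom = as.character(seqnames(grid)),
                      start = BiocGenerics::start(grid) - 1L,
                      end = BiocGenerics::end(grid),
                      gc_fraction = binGC(grid),
                      mappable_36mers = mappable36mers(grid),
                      reference_weight = referenceWeights(grid))
    write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read and write per-bin count tables
#'
#' Long TSV keyed to a grid file by bin order: columns `embryo_id`,
#' `bin` (1-based row index into the grid) and `count`.
#'
#' @param path TSV file path.
#' @return `readBinCounts()` returns a `data.frame`;
#'   `writeBinCounts()` invisibly returns the path.
#' @export
readBinCounts <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("embryo_id", "bin", "count")
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop("count table lacks column(s): ",
             paste(missing, collapse = ", "))
    tab
}

#' @rdname readBinCounts
#' @param counts named list of per-bin count vectors (names are embryo
#'   ids) or a single numeric vector.
#' @param embryoId id used when `counts` is a bare vector.
#' @export
writeBinCounts <- function(counts, path, embryoId = "sample") {
    if (!is.list(counts)) counts <- stats::setNames(list(counts), embryoId)
    tab <- do.call(rbind, lapply(names(counts), function(id)
        data.frame(embryo_id = id, bin = seq_along(counts[[id]]),
                   count = counts[[id]])))
    write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read and write mitochondrial pileup tables
#'
#' TSV with columns `position`, `ref_count`, `alt_count`.
#'
#' @param path TSV file path.
#' @return `readPileup()` returns a `data.frame`; `writePileup()`
#'   invisibly returns the path.
#' @export
readPileup <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("position", "ref_count", "alt_count")
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop("pileup lacks column(s): ", paste(missing, collapse = ", "))
    tab
}

#' @rdname readPileup
#' @param pileup pileup `data.frame`.
#' @export
writePileup <- function(pileup, path) {
    write.table(pileup, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write and read threshold models as JSON
#'
#' @param model a [ThresholdModel-class].
#' @param path JSON file path.
#' @export
writeThresholdModel <- function(model, path) {
    stopifnot(is(model, "ThresholdModel"))
    jsonlite::write_json(
        list(assay = model@assay, cutoff = model@cutoff,
             derivation = model@derivation,
             training_max_implanter = model@trainingMaxImplanter),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}

#' @rdname writeThresholdModel
#' @export
readThresholdModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("ThresholdModel", assay = x$assay, cutoff = x$cutoff,
        derivation = x$derivation,
        trainingMaxImplanter =
            if (is.null(x$training_max_implanter)) NA_real_
            else x$training_max_implanter)
}

#' Convert cohort metrics to a plain list
#'
#' @param metrics a [CohortMetrics-class].
#' @return a named list suitable for JSON serialization.
#' @export
metricsAsList <- function(metrics) {
    stopifnot(is(metrics, "CohortMetrics"))
    list(n_transferred = metrics@nTransferred,
         n_implanted = metrics@nImplanted,
         n_above = metrics@nAbove,
         n_above_implanted = metrics@nAboveImplanted,
         npv = metrics@npv,
         rate_below = metrics@rateBelow,
         rate_overall = metrics@rateOverall,
         flagged_nonimplanter_fraction =
             metrics@flaggedNonimplanterFraction)
}

#' The published 23-sample trophectoderm reference dataset
#'
#' The bundled per-sample values of the 23 euploid trophectoderm
#' biopsies assessed with both assays: sample id, qPCR relative
#' quantity (2^-ddCt), NGS mitochondrial percent, the printed
#' low/high classifications for both assays, and the clinical outcome
#' after transfer (21 known, 2 unknown). Used by the tests and the
#' worked examples to exercise classification and threshold evaluation
#' against published values.
#'
#' @return a 23-row `data.frame`: `sample_id`, `rq_qpcr`,
#'   `qpcr_class`, `ngs_percent`, `ngs_class`, `outcome`.
#' @examples
#' t3 <- table3Fixture()
#' table(classifyQpcr(t3$rq_qpcr) == t3$qpcr_class)
#' @export
table3Fixture <- function() {
    path <- system.file("extdata", "table3_te_samples.csv",
                        package = "mitoEmbryo", mustWork = TRUE)
    read.csv(path, stringsAsFactors = FALSE)
}
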