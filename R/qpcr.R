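#' @include utils.R
NULL

#' Aggregate a qPCR triplicate
#'
#' Averages three replicate cycle thresholds and flags noisy
#' triplicates. Aggregation is by arithmetic mean; a triplicate whose
#' sample standard deviation exceeds `maxSd` is flagged
#' `"high_replicate_sd"` but still quantified (flag-not-drop keeps the
#' pipeline total). Missing replicates are an error - no silent
#' imputation.
#'
#' @param ct numeric vector of exactly 3 finite cycle thresholds, each
#'   in `(0, ctMax]`.
#' @param maxSd replicate standard-deviation tolerance, cycles
#'   (default 0.5).
#' @param ctMax upper plausibility bound on a cycle threshold
#'   (default 40; the assay design runs 30 amplification cycles, so the
#'   cap is configurable).
#' @return a list with `mean`, `sd` and `qcFlag`
#'   (`"pass"` or `"high_replicate_sd"`).
#' @examples
#' aggregateTriplicates(c(20.0, 20.2, 19.8))
#' aggregateTriplicates(c(20.0, 20.0, 23.0))$qcFlag
#' @export
aggregateTriplicates <- function(ct, maxSd = 0.5, ctMax = 40) {
    if (length(ct) != 3L)
        stop("a triplicate must contain exactly 3 cycle thresholds")
    if (any(!is.finite(ct)))
        stop("missing or non-finite replicate; no imputation is applied")
    if (any(ct <= 0 | ct > ctMax))
        stop(sprintf("cycle thresholds must lie in (0, %g]", ctMax))
    s <- sd(ct)
    list(mean = mean(ct), sd = s,
         qcFlag = if (s > maxSd) "high_replicate_sd" else "pass")
}

#' Delta-Ct of a sample
#'
#' The mitochondrial-minus-Alu cycle-threshold difference,
#' `Ct_mt - Ct_alu`. Vectorized.
#'
#' @param ctMt,ctAlu mean cycle thresholds of the mitochondrial and Alu
#'   assays, cycles.
#' @return `ctMt - ctAlu`, cycles.
#' @examples
#' deltaCt(25, 20)
#' @export
deltaCt <- function(ctMt, ctAlu) {
    stopifnot(all(is.finite(ctMt)), all(is.finite(ctAlu)))
    ctMt - ctAlu
}

#' Relative mtDNA quantity by the 2^-ddCt method
#'
#' Normalizes a test sample's delta-Ct against the run-constant
#' reference sample's delta-Ct and converts to a relative quantity:
#' `ddCt = deltaCtTest - deltaCtReference`, `rq = 2^-ddCt`. The
#' reference sample's negated delta-Ct is the run's normalisation
#' factor; a perfect doubling per cycle (amplification efficiency 2) is
#' assumed throughout, as is standard for the ddCt method.
#'
#' @param deltaCtTest test-sample delta-Ct (`Ct_mt - Ct_alu`), cycles.
#' @param deltaCtReference reference-sample delta-Ct, one constant per
#'   analysis run, cycles.
#' @return a `data.frame` with `delta_ct`, `delta_delta_ct` and `rq`.
#' @examples
#' relativeQuantity(13, 5)$rq       # 2^-8
#' relativeQuantity(5, 5)$rq        # self-reference: 1
#' @export
relativeQuantity <- function(deltaCtTest, deltaCtReference) {
    stopifnot(all(is.finite(deltaCtTest)),
              length(deltaCtReference) == 1L,
              is.finite(deltaCtReference))
    ddct <- deltaCtTest - deltaCtReference
    data.frame(delta_ct = deltaCtTest, delta_delta_ct = ddct,
               rq = 2^(-ddct))
}

#' Classify a qPCR relative quantity against the viability threshold
#'
#' `"high_abnormal"` when the relative quantity strictly exceeds the
#' threshold, else `"low_normal"`. The inequality is strict: a value
#' exactly at the cutoff is low/normal.
#'
#' @param rq positive relative quantities (2^-ddCt scale).
#' @param threshold classification cutoff (default 0.003, the published
#'   qPCR viability threshold).
#' @return character vector in `{"low_normal", "high_abnormal"}`.
#' @examples
#' classifyQpcr(c(0.0164158, 0.00103, 0.003))
#' @export
classifyQpcr <- function(rq, threshold = 0.003) {
    if (any(!is.finite(rq) | rq <= 0))
        stop("relative quantities must be positive")
    .assertScalarNumber(threshold, "threshold", positive = TRUE)
    ifelse(rq > threshold, "high_abnormal", "low_normal")
}

#' Quantify a cohort's Ct table
#'
#' Runs the full ddCt pipeline over a long-format Ct table (as written
#' by [simulateQpcrTable()] or read with [readCtTable()]): triplicates
#' are aggregated per assay, delta-Ct and 2^-ddCt computed against the
#' run's reference delta-Ct, and each sample classified against the
#' viability threshold. A sample is QC-flagged when either assay's
#' triplicate is.
#'
#' @param ctTable `data.frame` with columns `embryo_id`, `assay`
#'   (`"mt"`/`"alu"`), `rep1`, `rep2`, `rep3`.
#' @param referenceDeltaCt the run-constant reference sample's
#'   delta-Ct, cycles.
#' @param maxSd,ctMax passed to [aggregateTriplicates()].
#' @param threshold passed to [classifyQpcr()].
#' @return a `data.frame` with one row per embryo: `embryo_id`,
#'   `ct_mt`, `ct_alu`, `delta_ct`, `delta_delta_ct`, `rq`, `qc_flag`,
#'   `class`.
#' @examples
#' cfg <- simulationConfig(ctNoiseSd = 0, seed = 1)
#' ct <- simulateQpcr(0.003, cfg, referenceDeltaCt = 8, embryoId = "E1")
#' quantifyCtTable(ct, referenceDeltaCt = 8)
#' @export
quantifyCtTable <- function(ctTable, referenceDeltaCt, maxSd = 0.5,
                            ctMax = 40, threshold = 0.003) {
    need <- c("embryo_id", "assay", "rep1", "rep2", "rep3")
    missing <- setdiff(need, names(ctTable))
    if (length(missing))
        stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
    ids <- unique(ctTable$embryo_id)
    rows <- lapply(ids, function(id) {
        sub <- ctTable[ctTable$embryo_id == id, , drop = FALSE]
        one <- function(a) {
            r <- sub[sub$assay == a, , drop = FALSE]
            if (nrow(r) != 1L)
                stop(sprintf("sample '%s': expected one '%s' triplicate",
                             id, a))
            aggregateTriplicates(as.numeric(r[, c("rep1", "rep2", "rep3")]),
                                 maxSd = maxSd, ctMax = ctMax)
        }
        mt <- one("mt"); alu <- one("alu")
        rqRow <- relativeQuantity(deltaCt(mt$mean, alu$mean),
                                  referenceDeltaCt)
        data.frame(embryo_id = id, ct_mt = mt$mean, ct_alu = alu$mean,
                   delta_ct = rqRow$delta_ct,
                   delta_delta_ct = rqRow$delta_delta_ct, rq = rqRow$rq,
                   qc_flag = if (mt$qcFlag == "pass" &&
                                 alu$qcFlag == "pass")
                       "pass" else "high_replicate_sd",
                   class = classifyQpcr(rqRow$rq, threshold),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
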